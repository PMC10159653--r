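---
title: "Alignment algorithms, memory modelling and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment algorithms, memory modelling and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pimalign)
```

## Scope and model

`pimalign` aligns DNA sequence pairs (a *pattern*, typically a read, and a
*text*, typically a reference slice) end to end over the four-letter
alphabet {A, C, G, T}. All scores are **costs to minimize**: a match costs
`a`, a mismatch `x`, and gaps cost either `g * e` (linear model) or
`o + g * e` (affine model) for a gap of `g` bases. With the default
penalty sets — `a=0, x=3, e=4` linear and `a=0, x=3, o=4, e=1` affine — a
perfect alignment scores 0. There is no similarity-maximization mode, no
local or semi-global alignment, and no clipping: every CIGAR must consume
the whole pattern (runs over {M, X, I}) and the whole text (runs over
{M, X, D}). The CIGAR alphabet is the extended SAM dialect with `M`
strictly meaning match — with `a = 0` the M/X distinction is what makes
the cost recomputable from the CIGAR alone, which is how `cigar_score()`
and `cigar_validate()` audit every traceback in the test suite.

Characters outside the alphabet (including N and IUPAC ambiguity codes)
are rejected at parse time rather than scored: the bitap masks and the
4-letter substitution logic would otherwise assign them silent,
meaningless costs.

## The five aligners

**Needleman–Wunsch** (`nw_align`) fills the full (m+1)×(n+1) cost table
under the linear gap model and walks back. Traceback ties are broken
diagonal (M/X) first, then D (consume text), then I (consume pattern) —
the recurrences do not determine this, so it is fixed for deterministic,
left-consistent output.

**Smith–Waterman–Gotoh** (`swg_align`) keeps the three-state affine
recurrence (overall/insertion/deletion). The three tables can be stored
*interleaved* — one record of three cells per (i, j), so a row fetch
touches all three states contiguously, the layout a DMA-based device
would use to fetch all three tables in one transfer — or as three
separate tables; a dedicated test holds the two layouts bit-identical.
Cells are kept in 32-bit integers internally; the modelled device stores
int16 cells, and every cost reachable under the supported lengths and
default penalties fits 16 bits well before the capacity ceilings bind,
so widening cannot change any reachable value while avoiding sentinel
overflow for the barred boundary states.

**Bitap with traceback** (`genasm_align`) computes the thresholded
unit-cost edit-distance recurrence bit-parallel: bit `b` of status vector
`R[j][d]` is set iff pattern prefix length `b+1` aligns to text prefix
`j` within `d` edits; the four contributions per step (match,
substitution, insertion, deletion) are the four intermediate vectors. All
(n+1)×(k+1) status vectors are retained so the traceback can emit one of
the four cases per step, preferring match > substitution > deletion >
insertion. Words are 64-bit, little-endian word order, and the multi-word
path is pinned against a single-wide-word reference for m ≤ 64. The score
is the plain edit distance; a pair whose distance exceeds `k` is
*rejected* (`success = FALSE`, score unset) — threshold semantics, not an
error. `k` defaults to `ceiling(error_rate * read_length)` via
`choose_k()`. We deliberately score this aligner unit-cost even though
affine-gap phrasing sometimes accompanies bitap aligners in the
literature: the algorithm is parameterized only by an edit threshold, no
affine weights exist for the bitap recurrence here, and unit cost is what
an independent Levenshtein oracle can certify.

**Wavefront alignment** (`wfa_align`) advances furthest-reaching offsets
per diagonal in increasing score order under the affine model (match
cost must be 0, which the classic formulation requires; the default
penalty set satisfies this). Diagonals are indexed `d = i - j` and the
stored offset is `i`, the pattern progress. The recurrence at score `s`
draws I/D from gap-open (`s-o-e`, M) and gap-extend (`s-e`, I/D) sources
and M from the mismatch source (`s-x`) and the new I/D; absent sources
are empty ranges. Exactness — equality with `swg_align` on every fuzzed
pair — is the suite's central acceptance property. The backtrace keeps
the full wavefront history (no recomputation or piggybacking): retention
is the simplest contract that supports full CIGAR output.

**Adaptive wavefront** (`wfa_adaptive_align`) trims outer diagonals
after each extension step once the M component spans more than
`min_wavefront_length` diagonals (default 10): a diagonal whose
antidiagonal progress `i + j` lags the best by more than
`max_distance_threshold` (default 50) is removed from the `lo`/`hi`
bounds. The defaults are the reference wavefront implementation's; the
trimmed score can only move up, so `adaptive >= exact` always, with
equality guaranteed whenever trimming never fires (the result carries a
`pruned` flag so tests can condition on exactly that). In practice, at
the study's settings (up to 5% edits), the adaptive score equals the
exact one on essentially every generated pair.

### The arena allocator

Wavefront components vary in size at run time, so the wavefront aligners
draw them from a per-worker bump allocator (`arena_new`, `arena_alloc`,
`arena_reset`): 8-byte-aligned offsets handed out front to back, freed
all at once between pairs. One arena per worker means no synchronization,
and the high-water mark equals the largest single-pair footprint across a
batch — both properties are tested. Exhaustion fails the *pair*
(`success = FALSE`, reason `"arena exhausted"`), never the batch.

The default arena capacity is 64 MB — the DRAM-bank tier of the modelled
hierarchy — rather than the 64-KB scratchpad tier. Because the backtrace
retains the whole wavefront history, its storage corresponds to the
bank-resident placement; a 64-KB arena only fits pairs up to roughly
200 bp at the study's edit rates and is available by passing
`arena_bytes = 65536` (or `--arena-bytes` on the command line) when
scratchpad-resident behaviour is the thing being studied.

Retained history costs Θ(s · #diagonals) bytes — about `3 (s+1) (2s+1)`
4-byte offsets for final score `s`. Since `s` grows with both length and
error rate, this is quadratic in read length at a fixed error rate
(measured: ~0.4 KB at 250 bp to ~70 KB at 2 kb, 1% edits), although it
remains far below the `3·m·n` int16 DP-table footprint throughout the
supported range. A linear-space wavefront variant would have to drop
retention and re-derive the traceback, which is out of scope here.

## The memory occupancy model

`footprint()`, `max_read_length()` and `auto_threads()` model the
capacity side of one processing-in-memory DRAM processing unit: a 64-KB
scratchpad (WRAM) and a 64-MB bank (MRAM) shared by up to 24 hardware
threads, int16 cells. For each algorithm there are two placements:
`WRAM_ONLY` puts the whole intermediate structure in the scratchpad;
`WRAM_MRAM` puts it in the bank and charges the scratchpad only the
working set (two table rows for the DP aligners, the staged vectors for
bitap, the up-to-7 wavefront components touched per step for the
wavefront aligners), capped at the structure size. Feasible threads =
`min(24, floor(wram / wram_per_thread), floor(mram / mram_per_thread))`.

The device's published arithmetic states results (a 175-bp ceiling and
61 KB per thread for the linear-gap aligner, 100 bp for the three-table
affine aligner), not every addend. The model's explicit overhead set —
2L bytes for the sequence pair, 2L bytes for the traceback operation
buffer, a 256-byte per-thread reserve — lands the scratchpad-only maxima
at 179 bp and 103 bp, inside both published brackets, and reproduces the
61,250-byte table term at 175 bp exactly. These constants were chosen
once, from the structure of the computation (two sequences, one output
op per consumed base, a small stack reserve), and are exposed in
`memory_config()` rather than hidden.

The bank-bound maxima do not follow from cost-table bytes alone: 2·L²
against 64 MB allows ~5.8 kb for the linear-gap aligner, while the
device's observed ceiling is near 4 kb. The model therefore has a
`traceback_in_mram` toggle (default on) adding one direction byte per
cell per table, which brings the bank-bound maxima to ~4.7 kb and
~2.7 kb; both accounting variants are reported rather than guessing one.

The wavefront footprint uses `s ≈ x · error_rate · L` (the all-mismatch
score bound with the default `x = 3`) as its wavefront-count proxy — the
algorithm's O(n·s) characterization offers nothing finer without running
the alignment. The model is capacity-only by design: cycle counts, DMA
latency and pipeline utilization are hardware measurements, not
reproducible arithmetic.

## Batch engine and formats

`run_batch()` partitions the input into contiguous, near-equal ranges
(`partition()`), runs each worker's range sequentially with its own
arena, and returns rows in input order. Workers share no mutable state,
so output is byte-identical across worker counts — asserted for 1/4/16
workers. Per-pair failures (capacity ceiling, threshold rejection, arena
exhaustion) become `FAIL` rows with an empty score and CIGAR in the
output table; a batch never drops or reorders entries. The two-level
device hierarchy (many DPUs × 24 threads) collapses to one worker pool
here: the scheme is embarrassingly parallel with no inter-thread
communication, so one level preserves the semantics, and
`auto_threads()` surfaces the device-side concurrency as a hint. The
`pimalign` exec script (`exec/pimalign`) exposes generate/align/plan
subcommands over these functions; wall-clock phase timings go to
standard error and are informational only — timing is not a test
surface.

Pair files use the reference wavefront tooling's generator dialect
(`>pattern` / `<text` in strict alternation, `#` comments), with a FASTA
mode (consecutive records paired) read through Biostrings. Results are a
minimal four-column TSV (id, status, score, CIGAR): no coordinates exist
for SAM emission, since these are global pairwise alignments.

## The synthetic generator

`generate_pairs()` emulates the generator used for the study's long-read
datasets: a uniform random text of the requested length; the pattern is
a copy with exactly `round(error_rate * length)` point mutations at
uniform positions, types uniform over mismatch/insertion/deletion,
mismatch bases always differing. The deterministic mutation count (not
Bernoulli-per-base) is what makes edit-distance bounds assertable:
planted edits can coincide or cancel, so the realized distance is *at
most* the planted count, and at 1 kb / 1% the mean realized distance
over 1,000 pairs sits in [8, 10] against a planted 10. Generation is
seeded, byte-reproducible, records its seed in the file header, and
restores the caller's RNG state.

What the generator does not emulate: sequencing error profiles
(homopolymer indel bias, quality-correlated errors), repeat structure,
or base-composition skew. Passing tests therefore certify algorithmic
correctness on uniform-background point-edit pairs — the regime the
study's synthetic sweeps cover — not robustness to real-read artefacts;
the real-read accessions the study also maps are deliberately out of
scope.

## Problem sizes and numerical choices

The test suite's acceptance campaign runs ~10,000 wavefront-vs-Gotoh
pairs (100/150/250 bp at 1/2/5% edits across ten seeds), ~5,000
linear-gap pairs against a top-down memoized-recursion oracle, ~10,000
bitap pairs against the Levenshtein oracle (base R's `adist`) including
rejection completeness, and 2,000 kilobase pairs for adaptive
dominance — sizes chosen so the whole suite completes in minutes on one
core while each cohort is large enough that a tie-break or boundary
defect cannot hide. Degenerate inputs (either sequence empty, length-1,
zero edits) are covered explicitly; empty-vs-empty aligns to an empty
CIGAR at score 0. Oracles are kept on independent routes: top-down
memoized recursion (and, as an external spot-check,
`Biostrings::pairwiseAlignment` under cost negation) against bottom-up
tables, `adist` against bitap, Gotoh against wavefronts — never the
implementation against itself.
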