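# pimalign

Global pairwise alignment of DNA sequence pairs with full traceback, plus
an analytical occupancy model of the two-tier scratchpad/DRAM-bank memory
hierarchy found on processing-in-memory (PIM) devices.

Sequence alignment is the classic approximate-string-matching step of
genomics pipelines, and on conventional hardware it is memory-bound:
little compute per byte of DP table touched. PIM devices attack this by
placing small cores next to the DRAM banks, but their tiny scratchpads
make *memory placement* — which intermediate structure lives where, and
how many threads then fit — the central design question. `pimalign` is a
desk-scale R embodiment of that workflow: the five alignment algorithms
such a device runs, a batch engine that dispatches pairs across
independent workers, and a capacity model that answers the placement
question analytically.

## What is implemented

All scores are **costs to minimize** (0 = perfect). Alignments are global
(end to end), CIGARs use the extended alphabet {M, X, I, D} with `M`
strictly a match, `I` consuming pattern only and `D` consuming text only.

| function | algorithm | model |
|---|---|---|
| `nw_align()` | Needleman–Wunsch, full table + traceback | linear gaps: gap of g costs g·e |
| `swg_align()` | Smith–Waterman–Gotoh, three interleaved tables | affine gaps: o + g·e |
| `genasm_align()` | bitap/GenASM-style bit-parallel DP + traceback | unit-cost edits, threshold k |
| `wfa_align()` | exact gap-affine wavefront algorithm + backtrace | affine gaps, match cost 0 |
| `wfa_adaptive_align()` | wavefront with outer-diagonal pruning | affine; score ≥ exact |

Default penalties are the study settings `a=0, x=3, e=4` (linear) and
`a=0, x=3, o=4, e=1` (affine). Around the aligners:

- `run_batch()` / `partition()` — deterministic batch dispatch; per-pair
  failures become `FAIL` rows, output is byte-identical across worker
  counts;
- `arena_new()` / `arena_alloc()` / `arena_reset()` — the per-worker bump
  allocator the wavefront aligners draw their components from;
- `footprint()`, `max_read_length()`, `auto_threads()` — the memory
  model: per-thread WRAM/MRAM bytes, feasible thread counts (≤ 24) and
  maximum read lengths per (algorithm, placement) pair;
- `generate_pairs()` — seeded synthetic pairs with planted point edits;
- `read_pairs()` / `write_alignments()` — the `>pattern`/`<text` pair
  dialect, FASTA pairing, and a four-column result TSV;
- `nw_cost_reference()`, `swg_cost_reference()`, `edit_distance()` —
  independent oracles (top-down memoized recursion; `adist`).

## Worked example

```r
library(pimalign)

pairs <- generate_pairs(3, 100, 0.05, seed = 7)  # 5 planted edits per pair
aln <- wfa_align(pairs[[1]])
aln
#> <alignment 0> WFA score=19 cigar=16M1D1X24M1X12M1X12M1I32M

swg_align(pairs[[1]])$score   # the Gotoh optimum -- always equal
#> [1] 19
cigar_score(aln$cigar, affine_penalties())
#> [1] 19
```

The CIGAR reads: 16 matches, a 1-base deletion (cost o+e = 5), a
mismatch (cost 3), 24 matches, ... — the five planted edits realized as
three mismatches and two 1-base gaps: 3·3 + 2·5 = 19. `cigar_score()`
recomputing the reported score from
the CIGAR (and `cigar_validate()` checking it consumes both sequences
exactly) is the package's standing audit of every traceback.

The memory model reproduces the device arithmetic:

```r
footprint("NW", "WRAM_ONLY", 175)
#> <footprint NW/WRAM_ONLY> L=175 e=0.020
#>   wram/thread: 62206 B   mram/thread: 0 B   table term: 61250 B
#>   feasible threads: 1 (feasible)
max_read_length("NW", "WRAM_ONLY")    # 179 -- the ~175-bp scratchpad ceiling
max_read_length("SWG", "WRAM_ONLY")   # 103 -- the ~100-bp ceiling
```

From a shell (the exec script installs with the package):

```sh
pimalign generate --n 1000 --length 150 --error 0.02 --seed 1 --output pairs.txt
pimalign align --algo wfa-adaptive --input pairs.txt --output out.tsv --workers 4
pimalign plan --algo swg --variant wram --length 100
```

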