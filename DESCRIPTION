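Package: pimalign
Title: Pairwise Sequence Alignment with Traceback and a Scratchpad-Memory
    Occupancy Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Five global pairwise alignment algorithms for DNA sequence
    pairs -- Needleman-Wunsch (linear gaps), Smith-Waterman-Gotoh (affine
    gaps), a bitap/GenASM-style bit-parallel aligner bounded by an edit
    distance threshold, and the exact and adaptive gap-affine wavefront
    algorithms -- each with full traceback and run-length CIGAR output.
    Includes a deterministic batch dispatch engine, reference cost oracles,
    readers and writers for sequence-pair and result files, a seeded
    synthetic sequence-pair generator with planted point edits, and an
    analytical occupancy model of a two-tier scratchpad/DRAM-bank memory
    hierarchy (as found on processing-in-memory devices) that reports
    per-thread footprints, feasible thread counts and maximum supported
    read lengths per algorithm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
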