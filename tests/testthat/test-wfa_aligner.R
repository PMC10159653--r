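test_that("arena allocator rounds to 8 bytes, resets, and reports exhaustion", {
  a <- arena_new(64)
  expect_identical(arena_alloc(a, 5), 0)
  expect_identical(arena_alloc(a, 3), 8)   # 5 rounded up to granularity
  expect_identical(arena_alloc(a, 16), 16)
  arena_reset(a)
  expect_identical(arena_alloc(a, 1), 0)
  st <- arena_stats(a)
  expect_identical(unname(st["high_water"]), 32) # survives reset
  expect_error(arena_alloc(a, 65), "exhausted")
  expect_error(arena_alloc(a, 0), "positive")
})

test_that("wavefront_extend advances M offsets by the exact-match run", {
  pair <- sequence_pair("ACGT", "ACGT")
  wf <- list(score = 0L, M = list(lo = 0L, hi = 0L, offset = 0L),
             I = NULL, D = NULL)
  ext <- wavefront_extend(wf, pair)
  expect_identical(ext$M$offset, 4L) # reaches the end of the text
  # no common first character on the active diagonal: unchanged
  pair2 <- sequence_pair("ACGT", "TACG")
  expect_identical(wavefront_extend(wf, pair2)$M$offset, 0L)
  # matches a naive per-diagonal character scan on random pairs
  for (s in 1:20) {
    p <- generate_pairs(1, 40, 0.1, seed = s)[[1]]
    pc <- strsplit(p$pattern, "")[[1]]; tc <- strsplit(p$text, "")[[1]]
    run <- 0L
    while (run < min(length(pc), length(tc)) && pc[run + 1] == tc[run + 1])
      run <- run + 1L
    expect_identical(wavefront_extend(wf, p)$M$offset, run)
  }
})

test_that("wavefront_next applies the gap-affine recurrence", {
  af <- affine_penalties(0, 3, 4, 1)
  pair <- sequence_pair("ACGTACGT", "TCGTACGA")
  # s = 0 wavefront: one mismatch consumed nothing yet, offset 0 at diag 0
  wf0 <- wavefront_extend(
    list(score = 0L, M = list(lo = 0L, hi = 0L, offset = 0L),
         I = NULL, D = NULL), pair)
  history <- list(wf0)
  # all sources null -> null wavefront
  null_wf <- wavefront_next(list(), 3L, af, pair)
  expect_null(null_wf$M); expect_null(null_wf$I); expect_null(null_wf$D)
  # s = x draws only from the mismatch source: same diagonal, offset + 1
  wf3 <- wavefront_next(history, 3L, af, pair)
  expect_null(wf3$I); expect_null(wf3$D)
  expect_identical(wf3$M$lo, 0L)
  expect_identical(wf3$M$offset, wf0$M$offset + 1L)
  # s = o + e opens gaps one diagonal to each side
  wf5 <- wavefront_next(list(wf0, NULL, NULL, NULL, NULL), 5L, af, pair)
  expect_identical(wf5$I$lo, 1L)
  expect_identical(wf5$D$lo, -1L)
})

test_that("pure-R wavefront driver reproduces the affine optimum", {
  af <- affine_penalties()
  for (s in 1:25) {
    p <- generate_pairs(1, 30, 0.1, seed = 1000 + s)[[1]]
    expect_identical(wfa_score_reference(p, af),
                     swg_align(p, af)$score)
  }
})

test_that("wfa_align is exact (equals Gotoh) with a cost-realizing CIGAR", {
  af <- affine_penalties()
  expect_identical(wfa_align(sequence_pair("ACGT", "ACGT"))$cigar, "4M")
  expect_identical(wfa_align(sequence_pair("AAAA", "AAGAA"))$score, 5L)
  pairs <- fuzz_pairs(300, c(5, 60, 200, 500), c(0, 0.02, 0.05), seed = 111)
  for (p in pairs) {
    a <- wfa_align(p, af)
    expect_identical(a$score, swg_align(p, af)$score)
    expect_true(cigar_validate(a$cigar, nchar(p$pattern), nchar(p$text)))
    expect_identical(cigar_score(a$cigar, af), a$score)
  }
})

test_that("adaptive pruning never undercuts the exact score", {
  af <- affine_penalties()
  expect_identical(wfa_adaptive_align(sequence_pair("ACGT", "ACGT"))$score, 0L)
  pairs <- fuzz_pairs(150, c(100, 400, 1000), c(0.02, 0.05), seed = 222)
  n_equal <- 0L
  for (p in pairs) {
    exact <- wfa_align(p, af)
    adapt <- wfa_adaptive_align(p, af)
    expect_gte(adapt$score, exact$score)
    if (!isTRUE(adapt$pruned)) expect_identical(adapt$score, exact$score)
    if (adapt$score == exact$score) n_equal <- n_equal + 1L
    expect_true(cigar_validate(adapt$cigar, nchar(p$pattern), nchar(p$text)))
    expect_identical(cigar_score(adapt$cigar, af), adapt$score)
  }
  expect_gt(n_equal, 0L)
  # a pair too short for the wavefront to exceed min length: identical result
  small <- generate_pairs(20, 8, 0.1, seed = 333)
  for (p in small) {
    a <- wfa_adaptive_align(p, af, min_wavefront_length = 50)
    expect_false(isTRUE(a$pruned))
    expect_identical(a$score, wfa_align(p, af)$score)
  }
})

test_that("arena exhaustion fails the pair gracefully, and resets reuse space", {
  p <- generate_pairs(1, 1000, 0.05, seed = 4)[[1]]
  a <- wfa_align(p, arena_bytes = 65536) # scratchpad-sized arena: too small
  expect_false(a$success)
  expect_match(a$reason, "arena")
  # high-water across a batch equals the max single-pair footprint
  arena <- arena_new(2^26)
  pairs <- generate_pairs(30, 300, 0.03, seed = 5)
  singles <- numeric(30)
  for (i in seq_along(pairs)) {
    solo <- arena_new(2^26)
    invisible(wfa_align(pairs[[i]], arena = solo))
    singles[i] <- arena_stats(solo)["high_water"]
    arena_reset(arena)
    invisible(wfa_align(pairs[[i]], arena = arena))
  }
  expect_identical(unname(arena_stats(arena)["high_water"]), max(singles))
})

test_that("wavefront memory stays in the O(s * diagonals) envelope", {
  # the retained history allocates at most s+1 wavefronts of three
  # components spanning at most 2s+1 diagonals each (4-byte offsets,
  # 8-byte arena granularity), and undercuts the full DP-table footprint
  for (L in c(250, 1000, 2000)) {
    a <- arena_new(2^27)
    p <- generate_pairs(1, L, 0.01, seed = 77)[[1]]
    aln <- wfa_align(p, arena = a)
    s <- aln$score
    hw <- arena_stats(a)[["high_water"]]
    expect_lte(hw, (s + 1) * 3 * ((2 * s + 1) * 4 + 8) + 16)
    expect_lt(hw, 3 * L * L * 2) # far below the three int16 DP tables
  }
})

test_that("wfa rejects nonzero match cost", {
  expect_error(wfa_align(sequence_pair("ACG", "ACG"),
                         affine_penalties(match = 1, mismatch = 3)),
               "match cost 0")
})
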