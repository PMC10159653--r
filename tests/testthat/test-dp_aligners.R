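test_that("nw_align handles identity, pure-gap and worked examples", {
  li <- linear_penalties(0, 3, 4)
  a <- nw_align(sequence_pair("ACGT", "ACGT"), li)
  expect_identical(a$score, 0L)
  expect_identical(a$cigar, "4M")
  b <- nw_align(sequence_pair("", "AAAA"), li)
  expect_identical(b$score, 16L)
  expect_identical(b$cigar, "4D")
  g <- sequence_pair("GATTACA", "GCATGCT")
  expect_identical(nw_align(g, li)$score, nw_cost_reference(g, li))
  expect_identical(nw_align(g, li)$score, nw_cost_memo_r("GATTACA", "GCATGCT", li))
})

test_that("swg_align handles identity and single-gap examples", {
  af <- affine_penalties(0, 3, 4, 1)
  a <- swg_align(sequence_pair("ACGT", "ACGT"), af)
  expect_identical(a$score, 0L)
  expect_identical(a$cigar, "4M")
  b <- swg_align(sequence_pair("AAAA", "AAAAGGG"), af)
  expect_identical(b$score, 7L)
  expect_identical(b$cigar, "4M3D")
})

test_that("dp aligners agree with memoized-recursion and external oracles", {
  li <- linear_penalties(); af <- affine_penalties()
  pairs <- fuzz_pairs(150, c(10, 60, 100), c(0.02, 0.05, 0.1), seed = 303)
  for (p in pairs) {
    expect_identical(nw_align(p, li)$score, nw_cost_reference(p, li))
    expect_identical(swg_align(p, af)$score, swg_cost_reference(p, af))
  }
  # spot-check both against an independent external implementation
  for (p in pairs[seq(1, 150, by = 10)]) {
    if (nchar(p$pattern) == 0 || nchar(p$text) == 0) next
    expect_identical(nw_align(p, li)$score, biostrings_cost(p$pattern, p$text, li))
    expect_identical(swg_align(p, af)$score, biostrings_cost(p$pattern, p$text, af))
  }
})

test_that("nw score respects the replace-then-gap upper bound", {
  li <- linear_penalties()
  pairs <- fuzz_pairs(80, c(5, 40, 120), c(0, 0.05, 0.2), seed = 404)
  for (p in pairs) {
    m <- nchar(p$pattern); n <- nchar(p$text)
    expect_lte(nw_align(p, li)$score,
               min(m, n) * li$mismatch + abs(m - n) * li$indel)
  }
})

test_that("swg with zero gap-open degenerates to nw with indel = gap_extend", {
  pairs <- fuzz_pairs(100, c(15, 70), c(0.03, 0.08), seed = 505)
  af0 <- affine_penalties(0, 3, 0, 4)
  li <- linear_penalties(0, 3, 4)
  for (p in pairs)
    expect_identical(swg_align(p, af0)$score, nw_align(p, li)$score)
})

test_that("interleaved and separate table layouts are bit-identical", {
  af <- affine_penalties()
  pairs <- fuzz_pairs(60, c(8, 50, 130), c(0.02, 0.07), seed = 606)
  for (p in pairs) {
    a <- swg_align(p, af, layout = "interleaved")
    b <- swg_align(p, af, layout = "separate")
    expect_identical(a$score, b$score)
    expect_identical(a$cigar, b$cigar)
  }
})

test_that("dp aligners enforce the configured capacity ceiling", {
  p <- generate_pairs(1, 300, 0, seed = 1)[[1]]
  expect_error(nw_align(p, max_length = 250), class = "pimalign_capacity_error")
  expect_error(swg_align(p, max_length = 250), class = "pimalign_capacity_error")
  expect_silent(nw_align(p, max_length = 300))
})
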