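test_that("cigar_score follows the gap-model algebra", {
  af <- affine_penalties(0, 3, 4, 1)
  li <- linear_penalties(0, 3, 4)
  expect_identical(cigar_score("4M", af), 0L)
  expect_identical(cigar_score("4M3D", af), 7L)   # one gap: o + 3e
  expect_identical(cigar_score("2M1X1I", li), 7L) # x + e
  expect_identical(cigar_score("1I2M1I", af), 10L) # two separate gap opens
  expect_identical(cigar_score("", af), 0L)
  expect_error(cigar_score("3Z", af), "unknown")
})

test_that("cigar_validate checks conservation and canonical encoding", {
  expect_true(cigar_validate("4M", 4, 4))
  expect_false(cigar_validate("4M", 4, 5))
  expect_false(cigar_validate("2M2M", 4, 4))
  expect_true(cigar_validate("2M1I1D", 3, 3))
  expect_false(cigar_validate("not a cigar", 1, 1))
  expect_false(cigar_validate("0M4M", 4, 4))
  expect_true(cigar_validate("", 0, 0))
})

test_that("sequence_pair validates alphabet, case and length ceiling", {
  p <- sequence_pair("acgt", "ACGG")
  expect_identical(p$pattern, "ACGT")
  expect_error(sequence_pair("ACGN", "ACGT"), "outside")
  expect_error(sequence_pair("ACGT", "ACGT", max_length = 3), "maximum")
  expect_error(linear_penalties(match = 5, mismatch = 3), "match cost")
  expect_error(affine_penalties(gap_open = -1), "non-negative")
})

test_that("every aligner's CIGAR validates and reproduces its score", {
  af <- affine_penalties(); li <- linear_penalties()
  unit <- linear_penalties(0, 1, 1) # bitap scores are unit-cost edits
  pairs <- fuzz_pairs(120, c(1, 5, 30, 80, 150), c(0, 0.02, 0.05), seed = 101)
  for (p in pairs) {
    m <- nchar(p$pattern); n <- nchar(p$text)
    expect_valid_alignment(nw_align(p, li), p, li)
    expect_valid_alignment(swg_align(p, af), p, af)
    expect_valid_alignment(wfa_align(p, af), p, af)
    g <- genasm_align(p, k = m + n) # threshold large enough to always pass
    expect_valid_alignment(g, p, unit)
  }
})

test_that("scores are invariant under pattern/text swap with I and D exchanged", {
  af <- affine_penalties(); li <- linear_penalties()
  pairs <- fuzz_pairs(60, c(20, 75), c(0.03, 0.06), seed = 202)
  for (p in pairs) {
    q <- sequence_pair(p$text, p$pattern, id = p$id)
    expect_identical(swg_align(p, af)$score, swg_align(q, af)$score)
    expect_identical(nw_align(p, li)$score, nw_align(q, li)$score)
    # swapped-direction CIGAR realizes the same cost with I <-> D
    cig <- chartr("ID", "DI", swg_align(p, af)$cigar)
    expect_identical(cigar_score(cig, af), swg_align(q, af)$score)
  }
})
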