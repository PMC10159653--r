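test_that("choose_k is the ceiling of error_rate * read_length", {
  expect_identical(choose_k(100, 0.05), 5L)
  expect_identical(choose_k(150, 0.01), 2L)
  expect_identical(choose_k(873, 0), 0L)
  # monotone in both arguments
  expect_true(all(diff(vapply(1:50 * 10, choose_k, 0L,
                              error_rate = 0.03)) >= 0))
  expect_true(all(diff(vapply(seq(0, 0.1, by = 0.01), function(e)
    choose_k(200, e), 0L)) >= 0))
})

test_that("pattern masks partition the pattern positions", {
  m <- build_pattern_masks("ACGT")
  expect_true(all(colSums(m) == 1))
  expect_true(m["A", 1] && m["C", 2] && m["G", 3] && m["T", 4])
  m2 <- build_pattern_masks("AAAA")
  expect_true(all(m2["A", ]))
  expect_identical(sum(m2), 4L)
  p <- generate_pairs(1, 211, 0, seed = 3)[[1]]$pattern
  expect_identical(sum(build_pattern_masks(p)), nchar(p))
  expect_error(build_pattern_masks("ACGN"), "outside")
})

test_that("bitap alignment matches the Levenshtein oracle within k", {
  expect_identical(genasm_align(sequence_pair("ACGT", "ACGT"), k = 3)$score, 0L)
  a <- genasm_align(sequence_pair("ACGT", "ACCT"), k = 3)
  expect_identical(a$score, 1L)
  expect_identical(sum(cigar_ops(a$cigar)$run[cigar_ops(a$cigar)$op == "X"]), 1L)
  expect_false(genasm_align(sequence_pair("AAAA", "TTTT"), k = 1)$success)

  pairs <- fuzz_pairs(400, c(10, 40, 150, 300), c(0, 0.01, 0.03), seed = 707)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    d <- edit_distance(p)
    k <- max(0L, min(10L, d + (i %% 4L) - 1L)) # sweeps k below, at, above d
    g <- genasm_align(p, k = k)
    if (d <= k) {
      expect_true(g$success)
      expect_identical(g$score, d)
      ops <- cigar_ops(g$cigar)
      # unit-cost model: exactly `score` non-M operation bases
      expect_identical(sum(ops$run[ops$op != "M"]), d)
    } else {
      expect_false(g$success)
      expect_true(is.na(g$score))
    }
  }
})

test_that("rejection is complete: success = FALSE iff distance exceeds k", {
  pairs <- fuzz_pairs(150, c(30, 90), c(0.04, 0.08), seed = 808)
  for (p in pairs) {
    d <- edit_distance(p)
    if (d > 0)
      expect_false(genasm_align(p, k = d - 1L)$success)
    expect_true(genasm_align(p, k = d)$success)
  }
})

test_that("multi-word path agrees with the single-wide-word reference", {
  pairs <- fuzz_pairs(200, c(3, 17, 33, 64), c(0, 0.05, 0.15), seed = 909)
  for (p in pairs) {
    if (nchar(p$pattern) > 64) next
    for (k in c(0L, 2L, 6L)) {
      full <- genasm_align(p, k = k)
      ref <- pimalign:::.genasm_score_u64_cpp(p$pattern, p$text, k)
      expect_identical(full$success, isTRUE(ref$success))
      if (full$success) expect_identical(full$score, ref$score)
    }
  }
})

test_that("error-rate parameterization derives k from the pattern length", {
  p <- generate_pairs(1, 150, 0.01, seed = 11)[[1]]
  g <- genasm_align(p, error_rate = 0.01)
  expect_true(g$success) # planted edits <= ceil(0.01 * 150) = 2
  expect_error(genasm_align(p), "either k or error_rate")
})
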