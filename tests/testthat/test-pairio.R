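test_that("seqpair files round-trip and carry 0-based ids", {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(c(">ACGT", "<ACGG"), f)
  ps <- read_pairs(f)
  expect_length(ps, 1L)
  expect_identical(ps[[1]]$pattern, "ACGT")
  expect_identical(ps[[1]]$text, "ACGG")
  expect_identical(ps[[1]]$id, "0")

  pairs <- generate_pairs(25, 90, 0.03, seed = 12)
  write_pairs(f, pairs)
  back <- read_pairs(f)
  expect_identical(lapply(back, `[[`, "pattern"),
                   lapply(pairs, `[[`, "pattern"))
  expect_identical(lapply(back, `[[`, "text"), lapply(pairs, `[[`, "text"))
  # write-read-write is byte-stable
  f2 <- tempfile()
  on.exit(unlink(f2), add = TRUE)
  write_pairs(f2, back)
  expect_identical(readLines(f), readLines(f2))
})

test_that("seqpair parser reports line-accurate errors", {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(c("<ACGT", ">ACGG"), f)
  expect_error(read_pairs(f), "line 1.*'>'")
  writeLines(c(">ACGT", "<ACGG", ">AAAA"), f)
  expect_error(read_pairs(f), "line 3")
  writeLines(c(">ACGT", "<ACNG"), f)
  expect_error(read_pairs(f), "line 2.*outside")
  writeLines(c("# comment", ">ACGT", "<ACGT"), f)
  expect_length(read_pairs(f), 1L)
  writeLines(character(0), f)
  expect_identical(read_pairs(f), list())
  expect_error(read_pairs(tempfile()), "no such file")
})

test_that("fasta mode pairs consecutive records and keeps header ids", {
  f <- tempfile(fileext = ".fa")
  on.exit(unlink(f))
  writeLines(c(">read1", "ACGTACGT", ">ref1", "ACGTACGA",
               ">read2", "TTTT", ">ref2", "TTAT"), f)
  ps <- read_pairs(f, format = "fasta")
  expect_length(ps, 2L)
  expect_identical(ps[[1]]$id, "read1")
  expect_identical(ps[[2]]$pattern, "TTTT")
  expect_identical(ps[[2]]$text, "TTAT")
  writeLines(c(">only", "ACGT"), f)
  expect_error(read_pairs(f, format = "fasta"), "even number")
})

test_that("alignment tables round-trip exactly, including failures", {
  f <- tempfile()
  on.exit(unlink(f))
  pairs <- generate_pairs(20, 70, 0.04, seed = 13)
  res <- run_batch(batch_job("genasm", k = 2L), pairs)
  write_alignments(f, res)
  lines <- readLines(f)
  expect_identical(length(lines), 20L)
  ok_rows <- which(res$status == "OK")
  fail_rows <- which(res$status == "FAIL")
  if (length(ok_rows))
    expect_identical(lines[ok_rows[1]],
                     sprintf("%s\tOK\t%d\t%s", res$id[ok_rows[1]],
                             res$score[ok_rows[1]], res$cigar[ok_rows[1]]))
  if (length(fail_rows))
    expect_identical(lines[fail_rows[1]],
                     sprintf("%s\tFAIL\t\t", res$id[fail_rows[1]]))
  back <- read_alignments(f)
  expect_identical(back$id, res$id)
  expect_identical(back$status, res$status)
  expect_identical(back$score, res$score)
  expect_identical(back$cigar[ok_rows], res$cigar[ok_rows])
})
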