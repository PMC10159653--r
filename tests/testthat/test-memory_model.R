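test_that("footprint reproduces the scratchpad capacity arithmetic", {
  fp <- footprint("NW", "WRAM_ONLY", 175)
  expect_identical(fp$dp_table_bytes, 175 * 175 * 2) # 61250 bytes
  expect_lt(fp$wram_per_thread, 65536)
  expect_identical(fp$feasible_threads, 1L)          # one thread at ~61 KB

  expect_false(footprint("NW", "WRAM_ONLY", 256)$feasible) # 131072 > 65536

  fp_swg <- footprint("SWG", "WRAM_ONLY", 100)
  expect_identical(fp_swg$dp_table_bytes, 3 * 100 * 100 * 2)
  expect_true(fp_swg$feasible)
  expect_identical(fp_swg$feasible_threads, 1L)
})

test_that("maximum read lengths bracket the device ceilings", {
  expect_true(max_read_length("NW", "WRAM_ONLY") %in% 170:180)
  expect_true(max_read_length("SWG", "WRAM_ONLY") %in% 100:104)
  # bank-bound variants with the traceback matrix accounted reach the
  # multi-kilobase range; without it the ceiling is higher
  with_tb <- max_read_length("NW", "WRAM_MRAM")
  no_tb <- max_read_length("NW", "WRAM_MRAM",
                           config = memory_config(traceback_in_mram = FALSE))
  expect_true(with_tb > 4000 && with_tb < 5500)
  expect_gt(no_tb, with_tb)
})

test_that("footprint and thread counts are monotone in read length", {
  for (algo in c("NW", "SWG", "GENASM", "WFA", "WFA_ADAPTIVE")) {
    for (variant in c("WRAM_ONLY", "WRAM_MRAM")) {
      lens <- c(10, 50, 100, 200, 500, 1000)
      fps <- lapply(lens, function(L) footprint(algo, variant, L, 0.02))
      wram <- vapply(fps, `[[`, 0, "wram_per_thread")
      threads <- vapply(fps, `[[`, 0L, "feasible_threads")
      expect_true(all(diff(wram) >= 0))
      expect_true(all(diff(threads) <= 0))
    }
  }
})

test_that("the bank-assisted variant never needs more scratchpad", {
  for (algo in c("NW", "SWG", "GENASM", "WFA", "WFA_ADAPTIVE")) {
    for (L in c(1, 3, 20, 100, 400, 2000)) {
      a <- footprint(algo, "WRAM_ONLY", L, 0.03)
      b <- footprint(algo, "WRAM_MRAM", L, 0.03)
      expect_lte(b$wram_per_thread, a$wram_per_thread)
      expect_gte(b$feasible_threads, a$feasible_threads)
    }
  }
})

test_that("auto_threads caps at 24, matches footprint, errors when infeasible", {
  expect_identical(auto_threads("NW", "WRAM_ONLY", 20), 24L)
  expect_identical(auto_threads("NW", "WRAM_ONLY", 175), 1L)
  expect_error(auto_threads("NW", "WRAM_ONLY", 300),
               class = "pimalign_capacity_error")
  expect_error(auto_threads("NW", "WRAM_ONLY", 300), "WRAM")
  # the two-tier variant admits at least as many threads
  expect_gte(auto_threads("SWG", "WRAM_MRAM", 100),
             auto_threads("SWG", "WRAM_ONLY", 100))
})

test_that("max_read_length is non-increasing in error rate where k matters", {
  e <- c(0, 0.01, 0.03, 0.05)
  for (algo in c("GENASM", "WFA")) {
    ml <- vapply(e, function(x) max_read_length(algo, "WRAM_ONLY", x), 0L)
    expect_true(all(diff(ml) <= 0))
  }
})
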