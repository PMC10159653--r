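# Analytical occupancy model of a two-tier scratchpad/DRAM-bank memory
# hierarchy as found on processing-in-DRAM devices: a 64-KB load/store
# scratchpad (WRAM) and a 64-MB DMA-accessed bank (MRAM) shared by up to
# 24 hardware threads. The model reports per-thread footprints for each
# (algorithm, placement-variant) pair, the number of threads that fit, and
# the maximum supported read length. Capacity only -- no latency model.

ALGORITHMS <- c("NW", "SWG", "GENASM", "WFA", "WFA_ADAPTIVE")
VARIANTS <- c("WRAM_ONLY", "WRAM_MRAM")

#' Memory hierarchy configuration
#'
#' Defaults describe one processing-in-memory DRAM processing unit: a
#' 64-KB scratchpad (WRAM), a 64-MB DRAM bank (MRAM), 24 hardware
#' threads, int16 DP cells. The overhead accounting -- 1 byte per sequence
#' base for the pair, 1 byte per operation for the traceback output
#' buffer, and a fixed per-thread reserve -- is an explicit, documented
#' constant set (the modelled device's published arithmetic states results,
#' not every addend).
#'
#' @param wram_bytes Scratchpad capacity per DPU (shared by its threads).
#' @param mram_bytes DRAM bank capacity per DPU.
#' @param max_threads Hardware threads per DPU.
#' @param dp_cell_bytes Bytes per DP/offset cell (int16 semantics).
#' @param per_thread_overhead_bytes Fixed reserve per thread (stack,
#'   DMA staging buffers).
#' @param traceback_in_mram For the WRAM+MRAM variants of the full-table
#'   aligners, also account a traceback direction matrix (1 byte per cell
#'   per table) in MRAM. On by default: without it the bank-bound maximum
#'   read lengths exceed the device's observed ceilings.
#' @return An object of class `memory_config`.
#' @export
memory_config <- function(wram_bytes = 65536, mram_bytes = 67108864,
                          max_threads = 24L, dp_cell_bytes = 2L,
                          per_thread_overhead_bytes = 256L,
                          traceback_in_mram = TRUE) {
  stopifnot(wram_bytes > 0, mram_bytes > 0, max_threads == 24L,
            dp_cell_bytes > 0, per_thread_overhead_bytes >= 0)
  structure(list(wram_bytes = wram_bytes, mram_bytes = mram_bytes,
                 max_threads = as.integer(max_threads),
                 dp_cell_bytes = as.integer(dp_cell_bytes),
                 per_thread_overhead_bytes = as.integer(per_thread_overhead_bytes),
                 traceback_in_mram = isTRUE(traceback_in_mram)),
            class = "memory_config")
}

#' Per-thread memory footprint of an (algorithm, variant) pair
#'
#' Computes the WRAM and MRAM bytes one worker thread needs to align a
#' pair of `read_length`-base sequences, and from them the number of
#' threads that fit the shared capacities.
#'
#' Accounting per algorithm (L = read length, c = cell bytes,
#' w = ceiling(L/64) * 8 bit-vector bytes, k = [choose_k()] threshold,
#' s = 3 * error_rate * L wavefront-count proxy for the default mismatch
#' cost):
#' \itemize{
#' \item NW: DP table L*L*c; WRAM+MRAM keeps two working rows in WRAM and
#'   the table (plus optional traceback matrix) in MRAM.
#' \item SWG: triples the table term (three interleaved tables).
#' \item GENASM: 4 pattern masks + 2(k+1) status vectors + 4 intermediate
#'   vectors of w bytes each; WRAM+MRAM moves masks and status vectors to
#'   MRAM, keeping the intermediate vectors and a staging slice in WRAM.
#' \item WFA / WFA_ADAPTIVE: retained wavefront history of roughly
#'   3 s^2 offsets; WRAM+MRAM keeps only the up-to-7 components touched
#'   per step (4 sources + 3 outputs, each spanning at most 2s+1
#'   diagonals) in WRAM. The adaptive variant's history diagonal span is
#'   capped by its pruning threshold.
#' }
#' Every variant additionally charges WRAM the sequence pair (2L bytes),
#' the traceback operation buffer (2L bytes) and the per-thread reserve.
#'
#' @param algorithm One of `"NW"`, `"SWG"`, `"GENASM"`, `"WFA"`,
#'   `"WFA_ADAPTIVE"`.
#' @param variant `"WRAM_ONLY"` (whole intermediate structure in the
#'   scratchpad) or `"WRAM_MRAM"` (structure in the bank, working set in
#'   the scratchpad).
#' @param read_length Read length in bases (> 0).
#' @param error_rate Expected edit rate; used by the k- and
#'   score-dependent algorithms.
#' @param config A [memory_config()].
#' @return An object of class `footprint_report`: algorithm, variant,
#'   read_length, error_rate, `wram_per_thread`, `mram_per_thread`,
#'   `dp_table_bytes` (the table/structure term alone),
#'   `feasible_threads` in `[0, 24]`, and `feasible`.
#' @examples
#' footprint("NW", "WRAM_ONLY", 175)   # DP-table term 61250, one thread
#' @export
footprint <- function(algorithm, variant, read_length, error_rate = 0.02,
                      config = memory_config()) {
  algorithm <- match.arg(toupper(algorithm), ALGORITHMS)
  variant <- match.arg(toupper(variant), VARIANTS)
  stopifnot(read_length > 0, error_rate >= 0, error_rate <= 1)
  L <- as.numeric(read_length)
  cbytes <- config$dp_cell_bytes
  pair_bytes <- 2 * L          # pattern + text, 1 byte/base
  tb_ops_bytes <- 2 * L        # traceback operation output buffer
  base_wram <- pair_bytes + tb_ops_bytes + config$per_thread_overhead_bytes

  wram <- NA_real_; mram <- 0; table_term <- NA_real_
  if (algorithm %in% c("NW", "SWG")) {
    ntab <- if (algorithm == "NW") 1 else 3
    table_term <- ntab * L * L * cbytes
    if (variant == "WRAM_ONLY") {
      wram <- table_term + base_wram
    } else {
      # current + previous row; never more than the whole table
      rows_wram <- min(2 * ntab * (L + 1) * cbytes, table_term)
      wram <- rows_wram + base_wram
      mram <- table_term +
        (if (config$traceback_in_mram) ntab * L * L else 0)
    }
  } else if (algorithm == "GENASM") {
    k <- choose_k(read_length, error_rate)
    w <- ceiling(L / 64) * 8
    masks <- 4 * w
    status <- 2 * (k + 1) * w
    intermediate <- 4 * w
    table_term <- masks + status
    if (variant == "WRAM_ONLY") {
      wram <- masks + status + intermediate + base_wram
    } else {
      wram <- intermediate + 2 * w + base_wram   # staging slice of 2 vectors
      mram <- masks + status
    }
  } else { # WFA / WFA_ADAPTIVE
    s <- ceiling(3 * error_rate * L)             # score proxy, mismatch cost 3
    span <- 2 * s + 1
    if (algorithm == "WFA_ADAPTIVE") span <- min(span, 2 * 50 + 1)
    history <- 3 * (s + 1) * span * cbytes       # M/I/D offsets per score
    table_term <- history
    if (variant == "WRAM_ONLY") {
      wram <- history + base_wram
    } else {
      # 4 source + 3 output components; never more than the whole history
      working <- min(7 * (2 * s + 1) * cbytes, history)
      wram <- working + base_wram
      mram <- history
    }
  }

  wram_threads <- floor(config$wram_bytes / wram)
  mram_threads <- if (mram > 0) floor(config$mram_bytes / mram) else Inf
  ft <- max(0, min(config$max_threads, wram_threads, mram_threads))
  structure(list(algorithm = algorithm, variant = variant,
                 read_length = read_length, error_rate = error_rate,
                 wram_per_thread = wram, mram_per_thread = mram,
                 dp_table_bytes = table_term,
                 wram_threads = wram_threads, mram_threads = mram_threads,
                 feasible_threads = as.integer(ft), feasible = ft >= 1),
            class = "footprint_report")
}

#' @export
print.footprint_report <- function(x, ...) {
  cat(sprintf("<footprint %s/%s> L=%d e=%.3f\n", x$algorithm, x$variant,
              x$read_length, x$error_rate))
  cat(sprintf("  wram/thread: %.0f B   mram/thread: %.0f B   table term: %.0f B\n",
              x$wram_per_thread, x$mram_per_thread, x$dp_table_bytes))
  cat(sprintf("  feasible threads: %d (%s)\n", x$feasible_threads,
              if (x$feasible) "feasible" else "infeasible"))
  invisible(x)
}

#' Maximum read length an (algorithm, variant) pair supports
#'
#' Largest read length with `feasible = TRUE`, found by bisection over
#' [footprint()]; monotonically non-increasing in `error_rate` for the
#' error-dependent algorithms.
#'
#' @inheritParams footprint
#' @return Integer length (0 when no length fits).
#' @examples
#' max_read_length("NW", "WRAM_ONLY")   # brackets the 175-bp ceiling
#' max_read_length("SWG", "WRAM_ONLY")  # brackets the 100-bp ceiling
#' @export
max_read_length <- function(algorithm, variant, error_rate = 0.02,
                            config = memory_config()) {
  ok <- function(L) footprint(algorithm, variant, L, error_rate, config)$feasible
  if (!ok(1)) return(0L)
  hi <- 1
  while (ok(hi * 2) && hi < 2^24) hi <- hi * 2
  lo <- hi; hi <- hi * 2
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (ok(mid)) lo <- mid else hi <- mid
  }
  as.integer(lo)
}

#' Worker-thread count for a feasible configuration
#'
#' Returns `feasible_threads` from [footprint()], used by the batch engine
#' as its per-worker concurrency hint; raises a capacity error naming the
#' binding constraint (WRAM vs MRAM) when nothing fits.
#'
#' @inheritParams footprint
#' @return Integer in `[1, 24]`.
#' @export
auto_threads <- function(algorithm, variant, read_length, error_rate = 0.02,
                         config = memory_config()) {
  fp <- footprint(algorithm, variant, read_length, error_rate, config)
  if (!fp$feasible) {
    binding <- if (fp$wram_threads < 1) "WRAM" else "MRAM"
    stop_capacity(sprintf(
      "infeasible configuration: %s capacity admits no thread (%s/%s at %d bp)",
      binding, algorithm, variant, as.integer(read_length)))
  }
  fp$feasible_threads
}
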