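# Batch dispatch: partition pairs evenly across workers, run the selected
# aligner per pair with a per-worker arena, collect results in input
# order. Workers share no mutable state, so results are deterministic and
# independent of the worker count by construction.

#' Partition n items evenly across workers
#'
#' Contiguous, disjoint ranges covering all items; sizes differ by at most
#' one, with the first `n_pairs %% n_workers` workers taking the extra
#' item.
#'
#' @param n_pairs Number of items (>= 0).
#' @param n_workers Number of workers (>= 1).
#' @return Data frame with columns `worker`, `start`, `end`, `size`
#'   (1-based inclusive ranges; an empty range has `size = 0` and
#'   `start > end`).
#' @examples
#' partition(10, 4)$size # 3 3 2 2
#' @export
partition <- function(n_pairs, n_workers) {
  stopifnot(n_pairs >= 0, n_workers >= 1)
  n_pairs <- as.integer(n_pairs); n_workers <- as.integer(n_workers)
  size <- rep(n_pairs %/% n_workers, n_workers) +
    (seq_len(n_workers) <= n_pairs %% n_workers)
  end <- cumsum(size)
  data.frame(worker = seq_len(n_workers), start = end - size + 1L,
             end = end, size = size)
}

#' Describe a batch alignment job
#'
#' @param algorithm One of `"nw"`, `"swg"`, `"genasm"`, `"wfa"`,
#'   `"wfa-adaptive"` (case-insensitive; `"wfa_adaptive"` also accepted).
#' @param penalties Penalty object for the DP/wavefront algorithms;
#'   defaults to [linear_penalties()] for NW and [affine_penalties()]
#'   otherwise.
#' @param k,error_rate Edit-distance threshold (or rate from which it is
#'   derived per pair) for the bitap aligner.
#' @param workers Number of workers the input is partitioned across.
#' @param variant Memory placement hint (`"wram"` or `"wram-mram"`)
#'   forwarded to [auto_threads()] for the concurrency hint; does not
#'   change alignment results.
#' @param arena_bytes Arena capacity per worker for the wavefront
#'   algorithms.
#' @param min_wavefront_length,max_distance_threshold Adaptive-pruning
#'   parameters (see [wfa_adaptive_align()]).
#' @param max_length Capacity ceiling per sequence; longer pairs are
#'   recorded as failed rather than aligned.
#' @return An object of class `batch_job`.
#' @export
batch_job <- function(algorithm, penalties = NULL, k = NULL,
                      error_rate = NULL, workers = 1L,
                      variant = c("wram", "wram-mram"), arena_bytes = 2^26,
                      min_wavefront_length = 10L,
                      max_distance_threshold = 50L, max_length = 10000L) {
  algo <- toupper(gsub("-", "_", algorithm))
  if (!algo %in% ALGORITHMS)
    stop_input(sprintf("unknown algorithm '%s'", algorithm))
  variant <- match.arg(variant)
  if (is.null(penalties))
    penalties <- if (algo == "NW") linear_penalties() else affine_penalties()
  stopifnot(workers >= 1)
  structure(list(algorithm = algo, penalties = penalties, k = k,
                 error_rate = error_rate, workers = as.integer(workers),
                 variant = if (variant == "wram") "WRAM_ONLY" else "WRAM_MRAM",
                 arena_bytes = arena_bytes,
                 min_wavefront_length = as.integer(min_wavefront_length),
                 max_distance_threshold = as.integer(max_distance_threshold),
                 max_length = as.integer(max_length)),
            class = "batch_job")
}

align_one <- function(job, pair, arena) {
  switch(job$algorithm,
    NW = nw_align(pair, job$penalties, max_length = job$max_length),
    SWG = swg_align(pair, job$penalties, max_length = job$max_length),
    GENASM = genasm_align(pair, k = job$k, error_rate = job$error_rate),
    WFA = wfa_align(pair, job$penalties, arena = arena,
                    arena_bytes = job$arena_bytes),
    WFA_ADAPTIVE = wfa_adaptive_align(pair, job$penalties,
                                      job$min_wavefront_length,
                                      job$max_distance_threshold,
                                      arena = arena,
                                      arena_bytes = job$arena_bytes))
}

#' Run a batch of alignments
#'
#' Partitions `pairs` across the job's workers with [partition()], aligns
#' each pair (each worker holding its own arena for the wavefront
#' algorithms, reset between pairs), and returns one row per pair in input
#' order regardless of the worker count. Per-pair failures -- capacity
#' ceilings, edit-distance threshold exceeded, arena exhaustion -- are
#' recorded as `status = "FAIL"` rows, never dropped.
#'
#' @param job A [batch_job()].
#' @param pairs List of [sequence_pair()] objects.
#' @return Data frame with columns `id`, `status` (`"OK"`/`"FAIL"`),
#'   `score`, `cigar`, `algorithm`, `reason`; attribute `threads_hint`
#'   carries the [auto_threads()] concurrency hint where computable.
#' @export
run_batch <- function(job, pairs) {
  stopifnot(inherits(job, "batch_job"), is.list(pairs))
  n <- length(pairs)
  parts <- partition(n, job$workers)
  uses_arena <- job$algorithm %in% c("WFA", "WFA_ADAPTIVE")

  rows <- vector("list", n)
  for (w in seq_len(nrow(parts))) {
    if (parts$size[w] == 0L) next
    arena <- if (uses_arena) arena_new(job$arena_bytes) else NULL
    for (idx in parts$start[w]:parts$end[w]) {
      pair <- pairs[[idx]]
      if (!is.null(arena)) arena_reset(arena)
      aln <- tryCatch(align_one(job, pair, arena),
                      pimalign_error = function(e) {
                        new_alignment(pair$id, NULL, NULL, job$algorithm,
                                      FALSE, reason = conditionMessage(e))
                      })
      rows[[idx]] <- data.frame(
        id = aln$pair_id,
        status = if (aln$success) "OK" else "FAIL",
        score = aln$score, cigar = aln$cigar,
        algorithm = aln$algorithm, reason = aln$reason,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(0), status = character(0),
                      score = integer(0), cigar = character(0),
                      algorithm = character(0), reason = character(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  hint <- tryCatch({
    if (n > 0)
      auto_threads(job$algorithm, job$variant,
                   max(vapply(pairs, function(p) nchar(p$pattern), 0L), 1L),
                   if (is.null(job$error_rate)) 0.02 else job$error_rate)
    else NA_integer_
  }, error = function(e) NA_integer_)
  attr(out, "threads_hint") <- hint
  out
}

#' Align a pair file end to end
#'
#' The whole workflow in one call: read pairs, run the batch, write the
#' result table. Returns the result data frame invisibly.
#'
#' @param input,output File paths.
#' @param job A [batch_job()].
#' @param format Input format (see [read_pairs()]).
#' @export
align_file <- function(input, output, job, format = c("seqpair", "fasta")) {
  pairs <- read_pairs(input, format = match.arg(format),
                      max_length = job$max_length)
  res <- run_batch(job, pairs)
  write_alignments(output, res)
  invisible(res)
}
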