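# Wavefront alignment (exact and adaptive) under affine penalties, with
# backtrace, plus the per-worker arena allocator its wavefront components
# are drawn from.

# ---- arena allocator -------------------------------------------------------

#' Per-worker arena allocator
#'
#' A bump allocator: `arena_alloc()` hands out 8-byte-aligned offsets
#' incrementally from beginning to end; `arena_reset()` frees everything at
#' once. One arena per worker, so no synchronization is ever needed. The
#' wavefront aligners draw all their per-score offset arrays from such an
#' arena and reset it between pairs; the high-water mark therefore tracks
#' the largest single-pair footprint, not the batch total.
#'
#' @param capacity_bytes Arena capacity in bytes. The default is the
#'   64-MB DRAM-bank tier of the modelled memory hierarchy (wavefront
#'   history is retained in full for the backtrace, which corresponds to
#'   bank-resident storage); pass 65536 to mirror the 64-KB scratchpad
#'   tier instead.
#' @return An external pointer of class `pimalign_arena`.
#' @examples
#' a <- arena_new(1024)
#' arena_alloc(a, 5) # 0
#' arena_alloc(a, 3) # 8 (5 rounds up to the 8-byte granularity)
#' arena_reset(a)
#' arena_alloc(a, 1) # 0 again
#' @export
arena_new <- function(capacity_bytes = 2^26) {
  p <- .arena_new_cpp(as.double(capacity_bytes))
  class(p) <- "pimalign_arena"
  p
}

#' @rdname arena_new
#' @param arena An arena from [arena_new()].
#' @param nbytes Number of bytes requested (> 0).
#' @return `arena_alloc()` returns the 8-byte-aligned byte offset of the
#'   allocation; an allocation that would overflow the capacity raises an
#'   arena-exhausted error.
#' @export
arena_alloc <- function(arena, nbytes) {
  .arena_alloc_cpp(arena, as.double(nbytes))
}

#' @rdname arena_new
#' @export
arena_reset <- function(arena) {
  .arena_reset_cpp(arena)
  invisible(arena)
}

#' @rdname arena_new
#' @return `arena_stats()` returns a named numeric vector with `capacity`,
#'   `cursor` and `high_water` (bytes).
#' @export
arena_stats <- function(arena) {
  .arena_stats_cpp(arena)
}

# ---- R reference wavefront operations -------------------------------------

# A wavefront set is a list(score, M, I, D); each component is either NULL
# or list(lo, hi, offset) with offset a vector indexed lo:hi (NA = absent
# diagonal). Offsets count pattern characters consumed; diagonal d = i - j.

wf_component <- function(lo, hi, offset) {
  stopifnot(lo <= hi, length(offset) == hi - lo + 1)
  list(lo = lo, hi = hi, offset = offset)
}

wf_get <- function(comp, d) {
  if (is.null(comp) || d < comp$lo || d > comp$hi) return(NA_integer_)
  comp$offset[d - comp$lo + 1L]
}

#' Extend a wavefront's M component along its diagonals
#'
#' Advances each furthest-reaching M offset by the length of the exact
#' match run along its diagonal; all other fields are unchanged. This is
#' the pure-R reference form of the operation used by the compiled
#' aligner.
#'
#' @param wf A wavefront set (list with `score`, `M`, `I`, `D`).
#' @param pair A [sequence_pair()].
#' @return The wavefront set with extended M offsets.
#' @export
wavefront_extend <- function(wf, pair) {
  if (is.null(wf$M)) stop_input("wavefront has no M component")
  p <- strsplit(pair$pattern, "")[[1]]; t <- strsplit(pair$text, "")[[1]]
  m <- length(p); n <- length(t)
  comp <- wf$M
  for (d in comp$lo:comp$hi) {
    i <- wf_get(comp, d)
    if (is.na(i)) next
    j <- i - d
    while (i < m && j < n && p[i + 1L] == t[j + 1L]) {
      i <- i + 1L; j <- j + 1L
    }
    comp$offset[d - comp$lo + 1L] <- i
  }
  wf$M <- comp
  wf
}

#' Compute the next wavefront from the score history
#'
#' Applies the gap-affine wavefront recurrence at score `s`: I/D components
#' take the furthest-reaching maxima of gap-open sources (score s-o-e, M)
#' and gap-extend sources (s-e, I/D) shifted one diagonal; the M component
#' maximizes over the mismatch source (s-x, M, offset + 1) and the new I/D.
#' Absent sources are treated as empty; a fully null result is a valid
#' wavefront.
#'
#' @param history List of wavefront sets, `history[[s + 1]]` holding score
#'   s (NULL where absent).
#' @param s Target score.
#' @param penalties An [affine_penalties()] object (match cost 0).
#' @param pair Optional [sequence_pair()]; when given, candidate offsets
#'   stepping outside the DP matrix are dropped.
#' @return A wavefront set for score `s` (components may be NULL).
#' @export
wavefront_next <- function(history, s, penalties, pair = NULL) {
  x <- penalties$mismatch; o <- penalties$gap_open; e <- penalties$gap_extend
  m <- if (is.null(pair)) Inf else nchar(pair$pattern)
  n <- if (is.null(pair)) Inf else nchar(pair$text)
  get_wf <- function(sc) {
    if (sc >= 0 && sc + 1 <= length(history)) history[[sc + 1]] else NULL
  }
  wx <- get_wf(s - x); woe <- get_wf(s - o - e); we <- get_wf(s - e)

  valid <- function(i, d) {
    !is.na(i) && i <= m && (i - d) >= 0 && (i - d) <= n
  }
  range_of <- function(...) {
    comps <- Filter(Negate(is.null), list(...))
    if (!length(comps)) return(NULL)
    as.integer(c(min(vapply(comps, `[[`, 0, "lo")),
                 max(vapply(comps, `[[`, 0, "hi"))))
  }
  max_na <- function(...) {
    v <- c(...)
    v <- v[!is.na(v)]
    if (!length(v)) NA_integer_ else max(v)
  }

  I_comp <- NULL
  r <- range_of(if (!is.null(woe)) woe$M, if (!is.null(we)) we$I)
  if (!is.null(r)) {
    lo <- r[1] + 1L; hi <- r[2] + 1L
    off <- vapply(lo:hi, function(d) {
      v <- max_na(wf_get(if (!is.null(woe)) woe$M, d - 1L),
                  wf_get(if (!is.null(we)) we$I, d - 1L))
      if (is.na(v)) return(NA_integer_)
      v <- v + 1L
      if (valid(v, d)) as.integer(v) else NA_integer_
    }, integer(1))
    if (any(!is.na(off))) I_comp <- wf_component(lo, hi, off)
  }

  D_comp <- NULL
  r <- range_of(if (!is.null(woe)) woe$M, if (!is.null(we)) we$D)
  if (!is.null(r)) {
    lo <- r[1] - 1L; hi <- r[2] - 1L
    off <- vapply(lo:hi, function(d) {
      v <- max_na(wf_get(if (!is.null(woe)) woe$M, d + 1L),
                  wf_get(if (!is.null(we)) we$D, d + 1L))
      if (is.na(v)) return(NA_integer_)
      if (valid(v, d)) as.integer(v) else NA_integer_
    }, integer(1))
    if (any(!is.na(off))) D_comp <- wf_component(lo, hi, off)
  }

  M_comp <- NULL
  r <- range_of(if (!is.null(wx)) wx$M, I_comp, D_comp)
  if (!is.null(r)) {
    lo <- r[1]; hi <- r[2]
    off <- vapply(lo:hi, function(d) {
      mm <- wf_get(if (!is.null(wx)) wx$M, d)
      if (!is.na(mm)) {
        mm <- mm + 1L
        if (!valid(mm, d)) mm <- NA_integer_
      }
      v <- max_na(mm, wf_get(I_comp, d), wf_get(D_comp, d))
      if (is.na(v)) NA_integer_ else as.integer(v)
    }, integer(1))
    if (any(!is.na(off))) M_comp <- wf_component(lo, hi, off)
  }

  list(score = s, M = M_comp, I = I_comp, D = D_comp)
}

#' Reference wavefront alignment score (pure R driver)
#'
#' Runs [wavefront_next()] / [wavefront_extend()] to completion and returns
#' the optimal affine-gap cost. Slow; intended as an executable statement
#' of the recurrence and as a cross-check of the compiled aligner on small
#' inputs.
#'
#' @param pair A [sequence_pair()].
#' @param penalties An [affine_penalties()] object with match cost 0.
#' @return Integer score.
#' @export
wfa_score_reference <- function(pair, penalties = affine_penalties()) {
  if (penalties$match != 0L)
    stop_input("wavefront alignment requires match cost 0")
  m <- nchar(pair$pattern); n <- nchar(pair$text)
  dT <- m - n
  wf0 <- wavefront_extend(
    list(score = 0L, M = wf_component(0L, 0L, 0L), I = NULL, D = NULL), pair)
  history <- list(wf0)
  s <- 0L
  s_max <- penalties$mismatch * min(m, n) +
    2L * (penalties$gap_open + penalties$gap_extend) +
    penalties$gap_extend * (abs(dT) + 2L) + penalties$mismatch + 1L
  repeat {
    wf <- history[[s + 1L]]
    if (!is.null(wf) && !is.null(wf$M) && identical(wf_get(wf$M, dT), m))
      return(s)
    s <- s + 1L
    if (s > s_max) stop("no alignment found") # unreachable for valid pairs
    nxt <- wavefront_next(history, s, penalties, pair)
    if (!is.null(nxt$M)) nxt <- wavefront_extend(nxt, pair)
    history[[s + 1L]] <- nxt
  }
}

# ---- compiled aligners -----------------------------------------------------

wfa_run <- function(pair, penalties, adaptive, min_wavefront_length,
                    max_distance_threshold, arena, arena_bytes, tag) {
  check_pair(pair)
  if (!inherits(penalties, "affine_penalties"))
    stop_input("wavefront alignment requires affine_penalties")
  if (penalties$match != 0L)
    stop_input("wavefront alignment requires match cost 0")
  r <- .wfa_align_cpp(pair$pattern, pair$text, penalties$mismatch,
                      penalties$gap_open, penalties$gap_extend, adaptive,
                      as.integer(min_wavefront_length),
                      as.integer(max_distance_threshold),
                      if (is.null(arena)) NULL else arena,
                      as.double(arena_bytes))
  if (!isTRUE(r$success))
    return(new_alignment(pair$id, NULL, NULL, tag, FALSE, reason = r$reason))
  aln <- new_alignment(pair$id, r$score, r$cigar, tag, TRUE)
  if (adaptive) aln$pruned <- isTRUE(r$pruned)
  aln
}

#' Exact gap-affine wavefront alignment (WFA)
#'
#' Computes the optimal affine-gap global alignment by advancing
#' furthest-reaching wavefronts in increasing score order, then backtraces
#' over the retained wavefront history to emit the CIGAR. The score always
#' equals [swg_align()]'s. All wavefront components are allocated through
#' the worker's arena, which is reset between pairs; if the arena is
#' exhausted the pair is reported failed (`success = FALSE`) rather than
#' crashing, so a batch can continue.
#'
#' @param pair A [sequence_pair()].
#' @param penalties An [affine_penalties()] object with match cost 0.
#' @param arena Optional shared arena from [arena_new()] (one per worker);
#'   when NULL a private arena of `arena_bytes` is used for this call.
#' @param arena_bytes Capacity of the private arena (see [arena_new()] for
#'   the default's rationale).
#' @return An `alignment` object.
#' @examples
#' wfa_align(sequence_pair("AAAA", "AAGAA")) # score 5: one 1-base gap, o+e
#' @export
wfa_align <- function(pair, penalties = affine_penalties(), arena = NULL,
                      arena_bytes = 2^26) {
  wfa_run(pair, penalties, FALSE, 0L, 0L, arena, arena_bytes, "WFA")
}

#' Adaptive wavefront alignment (heuristic)
#'
#' As [wfa_align()], but after each extension step a wavefront whose M
#' component spans more than `min_wavefront_length` diagonals has its
#' outer diagonals trimmed when their antidiagonal progress (i + j) lags
#' the best diagonal's by more than `max_distance_threshold`. The returned
#' score is an upper bound on the exact score, with equality whenever
#' trimming never removes an optimal diagonal (in particular whenever it
#' never fires).
#'
#' @inheritParams wfa_align
#' @param min_wavefront_length Pruning is disabled while the M component
#'   spans at most this many diagonals.
#' @param max_distance_threshold Maximum tolerated antidiagonal lag before
#'   an outer diagonal is trimmed.
#' @return An `alignment` object with an extra logical field `pruned`
#'   recording whether trimming ever removed a diagonal for this pair.
#' @export
wfa_adaptive_align <- function(pair, penalties = affine_penalties(),
                               min_wavefront_length = 10L,
                               max_distance_threshold = 50L, arena = NULL,
                               arena_bytes = 2^26) {
  if (min_wavefront_length < 0L) stop_input("min_wavefront_length must be >= 0")
  if (max_distance_threshold <= 0L)
    stop_input("max_distance_threshold must be > 0")
  wfa_run(pair, penalties, TRUE, min_wavefront_length, max_distance_threshold,
          arena, arena_bytes, "WFA_ADAPTIVE")
}
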