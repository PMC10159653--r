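# Full dynamic-programming aligners with traceback. These also serve as
# the exactness oracles for the wavefront aligner.

check_pair <- function(pair) {
  if (!inherits(pair, "sequence_pair"))
    stop_input("pair must be a sequence_pair object")
  pair
}

check_dp_capacity <- function(m, n, tables, max_length) {
  if (m > max_length || n > max_length)
    stop_capacity(sprintf(
      "sequence length (%d/%d bp) exceeds the configured DP ceiling (%d bp)",
      m, n, max_length))
  # keep the table allocation itself sane (tables * (m+1)*(n+1) int32 cells)
  if (tables * (m + 1) * (n + 1) * 4 > 2^31)
    stop_capacity("DP table would exceed the table budget")
  invisible(TRUE)
}

#' Global alignment with linear gap costs (Needleman-Wunsch)
#'
#' Fills the full (m+1) x (n+1) cost table and recovers the operations by
#' traceback. Ties are broken deterministically: diagonal (M/X) over D
#' (consume text) over I (consume pattern).
#'
#' @param pair A [sequence_pair()].
#' @param penalties A [linear_penalties()] object.
#' @param max_length Capacity ceiling on either sequence length; a longer
#'   pair raises a capacity error (the ceiling is configuration, not a
#'   hardware probe).
#' @return An `alignment` object: `pair_id`, `score` (minimum total cost),
#'   `cigar`, `algorithm`, `success`.
#' @examples
#' nw_align(sequence_pair("GATTACA", "GCATGCT"))
#' @export
nw_align <- function(pair, penalties = linear_penalties(),
                     max_length = getOption("pimalign.max_length", 10000L)) {
  check_pair(pair)
  if (!inherits(penalties, "linear_penalties"))
    stop_input("nw_align requires linear_penalties")
  m <- nchar(pair$pattern); n <- nchar(pair$text)
  check_dp_capacity(m, n, 1L, max_length)
  r <- .nw_align_cpp(pair$pattern, pair$text, penalties$match,
                     penalties$mismatch, penalties$indel)
  new_alignment(pair$id, r$score, r$cigar, "NW", TRUE)
}

#' Global alignment with affine gap costs (Smith-Waterman-Gotoh)
#'
#' Three-state (M/I/D) affine-gap global alignment with traceback over the
#' three-table recurrence. The three tables can be stored physically
#' interleaved -- one record of three cells per (i,j), so a row fetch
#' touches all three states contiguously -- or as separate tables; both
#' layouts produce bit-identical results.
#'
#' @inheritParams nw_align
#' @param penalties An [affine_penalties()] object.
#' @param layout Physical table layout, `"interleaved"` (default) or
#'   `"separate"`.
#' @return An `alignment` object (see [nw_align()]).
#' @examples
#' swg_align(sequence_pair("AAAA", "AAAAGGG"))  # score 7 = o + 3e, cigar 4M3D
#' @export
swg_align <- function(pair, penalties = affine_penalties(),
                      layout = c("interleaved", "separate"),
                      max_length = getOption("pimalign.max_length", 10000L)) {
  check_pair(pair)
  if (!inherits(penalties, "affine_penalties"))
    stop_input("swg_align requires affine_penalties")
  layout <- match.arg(layout)
  m <- nchar(pair$pattern); n <- nchar(pair$text)
  check_dp_capacity(m, n, 3L, max_length)
  r <- .swg_align_cpp(pair$pattern, pair$text, penalties$match,
                      penalties$mismatch, penalties$gap_open,
                      penalties$gap_extend, layout == "interleaved")
  new_alignment(pair$id, r$score, r$cigar, "SWG", TRUE)
}
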