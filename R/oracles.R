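# Reference cost oracles. These recompute optimal alignment costs by
# top-down memoized recursion (or, for edit distance, via base R's adist),
# independently of the table-filling aligners, and exist so that every
# aligner can be checked against an implementation that shares none of its
# code path.

#' Reference linear-gap alignment cost (memoized recursion)
#'
#' Top-down memoized recursion over the linear-gap cost recurrence.
#' Same contract as `nw_align(...)$score`, computed by a different route.
#'
#' @param pattern,text Sequences (plain strings) or a [sequence_pair()] in
#'   `pattern` with `text` missing.
#' @param penalties A [linear_penalties()] object.
#' @return Integer cost.
#' @export
nw_cost_reference <- function(pattern, text, penalties = linear_penalties()) {
  if (inherits(pattern, "sequence_pair")) {
    text <- pattern$text; pattern <- pattern$pattern
  }
  .nw_cost_ref_cpp(pattern, text, penalties$match, penalties$mismatch,
                   penalties$indel)
}

#' Reference affine-gap alignment cost (memoized three-state recursion)
#'
#' Top-down memoized recursion over the three-state (H/I/D) affine-gap
#' recurrence. Same contract as `swg_align(...)$score`.
#'
#' @inheritParams nw_cost_reference
#' @param penalties An [affine_penalties()] object.
#' @return Integer cost.
#' @export
swg_cost_reference <- function(pattern, text, penalties = affine_penalties()) {
  if (inherits(pattern, "sequence_pair")) {
    text <- pattern$text; pattern <- pattern$pattern
  }
  .swg_cost_ref_cpp(pattern, text, penalties$match, penalties$mismatch,
                    penalties$gap_open, penalties$gap_extend)
}

#' Unit-cost edit (Levenshtein) distance
#'
#' Thin wrapper over `utils::adist()`; the oracle for the bitap aligner.
#'
#' @inheritParams nw_cost_reference
#' @return Integer edit distance.
#' @export
edit_distance <- function(pattern, text) {
  if (inherits(pattern, "sequence_pair")) {
    text <- pattern$text; pattern <- pattern$pattern
  }
  as.integer(utils::adist(pattern, text))
}
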