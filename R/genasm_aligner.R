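# Bitap-based aligner with traceback (GenASM style): bit-parallel
# computation of all <= k-edit alignments, plus a traceback over the
# retained status bit-vectors.

#' Edit-distance threshold from read length and error rate
#'
#' `k = ceiling(error_rate * read_length)`; monotone in both arguments.
#'
#' @param read_length Read length in bases.
#' @param error_rate Expected edit rate in `[0, 1]`.
#' @return Integer threshold k.
#' @examples
#' choose_k(100, 0.05) # 5
#' choose_k(150, 0.01) # 2
#' @export
choose_k <- function(read_length, error_rate) {
  stopifnot(read_length >= 0, error_rate >= 0, error_rate <= 1)
  as.integer(ceiling(error_rate * read_length))
}

#' Pattern bit-masks for the bitap aligner
#'
#' One mask per alphabet character; entry `[c, i]` is `TRUE` iff
#' `pattern[i] == c`, so the four masks partition the pattern positions.
#' (The compiled aligner packs these into 64-bit words, little-endian word
#' order, bit i of a vector corresponding to pattern position i.)
#'
#' @param pattern Pattern string over A/C/G/T.
#' @param alphabet Character vector of alphabet symbols.
#' @return Logical matrix with one row per alphabet character and one
#'   column per pattern position.
#' @examples
#' build_pattern_masks("ACGT")
#' @export
build_pattern_masks <- function(pattern, alphabet = c("A", "C", "G", "T")) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  if (length(chars) && !all(chars %in% alphabet))
    stop_input("pattern contains characters outside the alphabet")
  masks <- vapply(alphabet, function(a) chars == a,
                  logical(length(chars)))
  m <- matrix(masks, nrow = length(alphabet), ncol = length(chars),
              byrow = TRUE, dimnames = list(alphabet, NULL))
  m
}

#' Bitap alignment bounded by an edit-distance threshold
#'
#' Computes the unit-cost edit distance d between pattern and text with a
#' bit-parallel thresholded recurrence; if `d <= k` the per-step status
#' vectors retained for every text position are walked back to emit one of
#' four cases per step (match, substitution, deletion, insertion; ties
#' broken in that order). If `d > k` the pair is rejected: `success =
#' FALSE` with the score unset, mirroring the semantics of an edit-distance
#' threshold filter.
#'
#' @param pair A [sequence_pair()].
#' @param k Maximum number of edits allowed; alternatively give
#'   `error_rate` and k is derived via [choose_k()] from the pattern
#'   length.
#' @param error_rate Optional edit rate used when `k` is missing.
#' @param max_vector_bytes Budget for the retained status vectors; a pair
#'   whose (n+1) x (k+1) bit-vector store would exceed it raises a
#'   capacity error.
#' @return An `alignment` object; `score` equals the edit distance and the
#'   CIGAR contains exactly `score` non-M operation bases.
#' @examples
#' genasm_align(sequence_pair("ACGT", "ACCT"), k = 3) # score 1
#' @export
genasm_align <- function(pair, k = NULL, error_rate = NULL,
                         max_vector_bytes = getOption(
                           "pimalign.genasm_budget", 256 * 2^20)) {
  check_pair(pair)
  m <- nchar(pair$pattern); n <- nchar(pair$text)
  if (is.null(k)) {
    if (is.null(error_rate))
      stop_input("supply either k or error_rate")
    k <- choose_k(m, error_rate)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 0L) stop_input("k must be >= 0")
  words <- max(1L, ceiling(m / 64))
  if ((n + 1) * (k + 1) * words * 8 > max_vector_bytes)
    stop_capacity("bit-vector store exceeds the configured budget")
  r <- .genasm_align_cpp(pair$pattern, pair$text, k)
  if (!isTRUE(r$success))
    return(new_alignment(pair$id, NULL, NULL, "GENASM", FALSE,
                         reason = sprintf("edit distance exceeds k = %d", k)))
  new_alignment(pair$id, r$score, r$cigar, "GENASM", TRUE)
}
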