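# Shared domain types, scoring conventions, and CIGAR algebra.
#
# Scores throughout the package are COSTS to be minimized: 0 is a perfect
# alignment. All alignments are global (end to end); the CIGAR alphabet is
# the extended SAM-style {M, X, I, D} with M strictly meaning match,
# I consuming pattern only and D consuming text only.

#' Construct a sequence pair
#'
#' A pattern (read) and a text (reference) over the DNA alphabet
#' \{A, C, G, T\}, to be aligned end to end.
#'
#' @param pattern Pattern (read) sequence, a single string over A/C/G/T.
#' @param text Text (reference) sequence, same alphabet.
#' @param id Identifier carried into alignment results.
#' @param max_length Maximum accepted length for either sequence; longer
#'   input raises a capacity error.
#' @return An object of class `sequence_pair` with fields `id`, `pattern`,
#'   `text`.
#' @examples
#' sequence_pair("ACGT", "ACGG")
#' @export
sequence_pair <- function(pattern, text, id = "0", max_length = 10000L) {
  stopifnot(is.character(pattern), length(pattern) == 1L,
            is.character(text), length(text) == 1L)
  pattern <- toupper(pattern)
  text <- toupper(text)
  if (!grepl("^[ACGT]*$", pattern))
    stop_input("pattern contains characters outside {A,C,G,T}")
  if (!grepl("^[ACGT]*$", text))
    stop_input("text contains characters outside {A,C,G,T}")
  if (nchar(pattern) > max_length || nchar(text) > max_length)
    stop_capacity(sprintf("sequence length exceeds the configured maximum (%d)",
                          max_length))
  structure(list(id = as.character(id), pattern = pattern, text = text),
            class = "sequence_pair")
}

#' @export
print.sequence_pair <- function(x, ...) {
  cat(sprintf("<sequence_pair %s> pattern: %d bp, text: %d bp\n",
              x$id, nchar(x$pattern), nchar(x$text)))
  invisible(x)
}

#' Linear gap penalties
#'
#' Non-negative costs: `match` per matching base, `mismatch` per
#' substituted base, `indel` per inserted or deleted base. A gap of length
#' g costs g * indel. Defaults are the evaluation setting a=0, x=3, e=4.
#'
#' @param match,mismatch,indel Non-negative integer costs.
#' @return An object of class `linear_penalties`.
#' @export
linear_penalties <- function(match = 0L, mismatch = 3L, indel = 4L) {
  p <- list(match = as.integer(match), mismatch = as.integer(mismatch),
            indel = as.integer(indel))
  if (any(vapply(p, function(v) is.na(v) || v < 0L, logical(1))))
    stop_input("penalties must be non-negative integers")
  if (p$match > p$mismatch)
    stop_input("match cost must not exceed mismatch cost")
  structure(p, class = "linear_penalties")
}

#' Affine gap penalties
#'
#' Non-negative costs under the affine gap model: a gap of length g costs
#' `gap_open + g * gap_extend`. Defaults are the evaluation setting
#' a=0, x=3, o=4, e=1.
#'
#' @param match,mismatch,gap_open,gap_extend Non-negative integer costs.
#' @return An object of class `affine_penalties`.
#' @export
affine_penalties <- function(match = 0L, mismatch = 3L, gap_open = 4L,
                             gap_extend = 1L) {
  p <- list(match = as.integer(match), mismatch = as.integer(mismatch),
            gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
  if (any(vapply(p, function(v) is.na(v) || v < 0L, logical(1))))
    stop_input("penalties must be non-negative integers")
  if (p$match > p$mismatch)
    stop_input("match cost must not exceed mismatch cost")
  structure(p, class = "affine_penalties")
}

new_alignment <- function(pair_id, score, cigar, algorithm, success,
                          reason = NA_character_) {
  structure(list(pair_id = as.character(pair_id),
                 score = if (is.null(score)) NA_integer_ else as.integer(score),
                 cigar = if (is.null(cigar)) NA_character_ else cigar,
                 algorithm = algorithm, success = isTRUE(success),
                 reason = reason),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  if (x$success)
    cat(sprintf("<alignment %s> %s score=%d cigar=%s\n", x$pair_id,
                x$algorithm, x$score, x$cigar))
  else
    cat(sprintf("<alignment %s> %s FAILED (%s)\n", x$pair_id, x$algorithm,
                x$reason))
  invisible(x)
}

#' Parse a CIGAR string into an operations table
#'
#' @param cigar CIGAR text such as `"23M1X76M"` over the extended alphabet
#'   M (match), X (mismatch), I (insertion into pattern), D (deletion from
#'   pattern / base only in text).
#' @return A data frame with columns `op` (character) and `run` (integer).
#' @examples
#' cigar_ops("2M1X1I")
#' @export
cigar_ops <- function(cigar) {
  stopifnot(is.character(cigar), length(cigar) == 1L, !is.na(cigar))
  if (cigar == "")
    return(data.frame(op = character(0), run = integer(0)))
  tok <- regmatches(cigar, gregexpr("([0-9]+)([A-Za-z])", cigar))[[1]]
  if (length(tok) == 0L || sum(nchar(tok)) != nchar(cigar))
    stop_input(sprintf("malformed CIGAR string: '%s'", cigar))
  op <- substr(tok, nchar(tok), nchar(tok))
  run <- as.integer(substr(tok, 1L, nchar(tok) - 1L))
  bad <- setdiff(unique(op), c("M", "X", "I", "D"))
  if (length(bad))
    stop_input(sprintf("unknown CIGAR op code(s): %s",
                       paste(bad, collapse = ", ")))
  data.frame(op = op, run = run, stringsAsFactors = FALSE)
}

#' Score a CIGAR under a penalty set
#'
#' Recomputes the alignment cost implied by a run-length encoded CIGAR:
#' each M run contributes `run * match`, each X run `run * mismatch`; a
#' maximal I or D run of length g contributes `gap_open + g * gap_extend`
#' under affine penalties and `g * indel` under linear penalties. The gap
#' model is carried by the class of `penalties`.
#'
#' @param cigar CIGAR string or the data frame from [cigar_ops()].
#' @param penalties A [linear_penalties()] or [affine_penalties()] object.
#' @return Non-negative integer cost.
#' @examples
#' cigar_score("4M3D", affine_penalties())   # 4 + 3*1 = 7
#' cigar_score("2M1X1I", linear_penalties()) # 3 + 4 = 7
#' @export
cigar_score <- function(cigar, penalties) {
  ops <- if (is.data.frame(cigar)) cigar else cigar_ops(cigar)
  if (nrow(ops) == 0L) return(0L)
  if (any(ops$run < 1L)) stop_input("CIGAR runs must be >= 1")
  if (inherits(penalties, "affine_penalties")) {
    per_op <- ifelse(ops$op == "M", ops$run * penalties$match,
              ifelse(ops$op == "X", ops$run * penalties$mismatch,
                     penalties$gap_open + ops$run * penalties$gap_extend))
  } else if (inherits(penalties, "linear_penalties")) {
    per_op <- ifelse(ops$op == "M", ops$run * penalties$match,
              ifelse(ops$op == "X", ops$run * penalties$mismatch,
                     ops$run * penalties$indel))
  } else {
    stop_input("penalties must be linear_penalties or affine_penalties")
  }
  as.integer(sum(per_op))
}

#' Validate a CIGAR against sequence lengths
#'
#' Checks the two conservation sums of a global alignment -- runs over
#' \{M, X, I\} must total the pattern length m and runs over \{M, X, D\}
#' the text length n -- and that the encoding is canonical (adjacent runs
#' differ in op, all runs >= 1). Returns `FALSE` rather than raising on
#' malformed input.
#'
#' @param cigar CIGAR string.
#' @param m Pattern length.
#' @param n Text length.
#' @return `TRUE` or `FALSE`.
#' @examples
#' cigar_validate("4M", 4, 4)    # TRUE
#' cigar_validate("2M2M", 4, 4)  # FALSE: non-canonical
#' @export
cigar_validate <- function(cigar, m, n) {
  ops <- tryCatch(cigar_ops(cigar), error = function(e) NULL)
  if (is.null(ops)) return(FALSE)
  if (any(ops$run < 1L)) return(FALSE)
  if (nrow(ops) > 1L && any(ops$op[-1L] == ops$op[-nrow(ops)])) return(FALSE)
  pat <- sum(ops$run[ops$op %in% c("M", "X", "I")])
  txt <- sum(ops$run[ops$op %in% c("M", "X", "D")])
  pat == m && txt == n
}

# swap I and D runs in a CIGAR (pattern/text exchange)
cigar_swap_id <- function(cigar) {
  chartr("ID", "DI", cigar)
}
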