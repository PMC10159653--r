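# Seeded synthetic sequence-pair generator: random texts with a planted
# fraction of point edits, emulating the reference wavefront tooling's
# generator so every aligner is testable without any download.

#' Generate synthetic sequence pairs with planted edits
#'
#' For each pair the text is uniform random over \{A,C,G,T\} of the given
#' length; the pattern starts as a copy of the text and receives exactly
#' `round(error_rate * length)` point mutations at uniformly chosen
#' positions, each mutation type uniform over mismatch / insertion /
#' deletion (a mismatch base always differs from the original). Planted
#' edits can coincide or cancel, so the realized edit distance is at most
#' the planted count. Output is deterministic for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param n_pairs Number of pairs (>= 0).
#' @param length Text length in bases (>= 1).
#' @param error_rate Planted edit fraction; the device study sweeps 0-5%.
#' @param seed Integer seed driving the generator.
#' @return List of [sequence_pair()] objects with ids `"0"`, `"1"`, ...
#' @examples
#' p <- generate_pairs(1, 100, 0.02, seed = 7)[[1]]
#' nchar(p$text)
#' @export
generate_pairs <- function(n_pairs, length, error_rate, seed) {
  if (n_pairs < 0 || length < 1 || error_rate < 0 || error_rate > 1)
    stop_input("invalid generator parameters")
  seed <- as.integer(seed)
  if (is.na(seed)) stop_input("seed must be an integer")

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  n_mut <- round(error_rate * length)
  lapply(seq_len(n_pairs), function(i) {
    text <- sample(DNA_BASES, length, replace = TRUE)
    pat <- plant_mutations(text, n_mut)
    sequence_pair(paste(pat, collapse = ""), paste(text, collapse = ""),
                  id = as.character(i - 1L),
                  max_length = max(10000L, length + n_mut))
  })
}

plant_mutations <- function(chars, n_mut) {
  for (i in seq_len(n_mut)) {
    len <- length(chars)
    type <- sample.int(3L, 1L)
    if (len == 0L) type <- 2L # only insertion possible
    if (type == 1L) {         # mismatch: always a different base
      pos <- sample.int(len, 1L)
      chars[pos] <- sample(setdiff(DNA_BASES, chars[pos]), 1L)
    } else if (type == 2L) {  # insertion into the pattern
      pos <- sample.int(len + 1L, 1L)
      chars <- append(chars, sample(DNA_BASES, 1L), after = pos - 1L)
    } else {                  # deletion from the pattern
      pos <- sample.int(len, 1L)
      chars <- chars[-pos]
    }
  }
  chars
}

#' Generate pairs and write them to a seqpair file
#'
#' Writes [generate_pairs()] output in seqpair format with the generator
#' parameters (including the seed) recorded in a leading comment line.
#'
#' @inheritParams generate_pairs
#' @param path Output file.
#' @return The path, invisibly.
#' @export
generate_pairs_file <- function(path, n_pairs, length, error_rate, seed) {
  pairs <- generate_pairs(n_pairs, length, error_rate, seed)
  write_pairs(path, pairs,
              comment = sprintf("pimalign generate n=%d length=%d error=%g seed=%d",
                                n_pairs, length, error_rate, seed))
  invisible(path)
}
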