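# Readers and writers for sequence-pair files and alignment results.
#
# The native "seqpair" dialect is the generator format of the reference
# wavefront tooling: the pattern line is prefixed ">", the text line "<",
# in strict alternation. Lines beginning "#" are comments (the synthetic
# generator records its seed in one). The FASTA mode pairs consecutive
# records (pattern then text).

#' Read sequence pairs
#'
#' @param path Input file.
#' @param format `"seqpair"` (alternating `>pattern` / `<text` lines) or
#'   `"fasta"` (two interleaved records per pair, read via Biostrings).
#' @param max_length Per-sequence capacity ceiling.
#' @return List of [sequence_pair()] objects, in file order. Ids are
#'   0-based indices unless FASTA headers provide names. Sequences are
#'   case-folded to upper case; characters outside \{A,C,G,T\} (including
#'   N and IUPAC ambiguity codes) are rejected with a line-accurate parse
#'   error rather than silently scored.
#' @export
read_pairs <- function(path, format = c("seqpair", "fasta"),
                       max_length = 10000L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  if (format == "fasta") return(read_pairs_fasta(path, max_length))

  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(list())
  if (length(lines) %% 2L != 0L)
    stop_input(sprintf(
      "line %d: dangling '>' record without a matching '<' line",
      lineno[length(lineno)]))
  pairs <- vector("list", length(lines) %/% 2L)
  for (i in seq_along(pairs)) {
    pl <- lines[2L * i - 1L]; tl <- lines[2L * i]
    pn <- lineno[2L * i - 1L]; tn <- lineno[2L * i]
    if (!startsWith(pl, ">"))
      stop_input(sprintf("line %d: expected a '>' pattern line", pn))
    if (!startsWith(tl, "<"))
      stop_input(sprintf("line %d: expected a '<' text line", tn))
    pat <- toupper(sub("^>", "", pl)); txt <- toupper(sub("^<", "", tl))
    if (!grepl("^[ACGT]*$", pat))
      stop_input(sprintf("line %d: pattern has characters outside {A,C,G,T}",
                         pn))
    if (!grepl("^[ACGT]*$", txt))
      stop_input(sprintf("line %d: text has characters outside {A,C,G,T}",
                         tn))
    pairs[[i]] <- sequence_pair(pat, txt, id = as.character(i - 1L),
                                max_length = max_length)
  }
  pairs
}

read_pairs_fasta <- function(path, max_length) {
  seqs <- Biostrings::readDNAStringSet(path)
  n <- length(seqs)
  if (n == 0L) return(list())
  if (n %% 2L != 0L)
    stop_input("FASTA pair file must contain an even number of records")
  txts <- toupper(as.character(seqs))
  hdrs <- names(seqs)
  lapply(seq_len(n %/% 2L), function(i) {
    pat <- txts[[2L * i - 1L]]; txt <- txts[[2L * i]]
    if (!grepl("^[ACGT]*$", pat) || !grepl("^[ACGT]*$", txt))
      stop_input(sprintf(
        "FASTA pair %d: characters outside {A,C,G,T} are not supported", i))
    id <- hdrs[[2L * i - 1L]]
    if (is.null(id) || !nzchar(id)) id <- as.character(i - 1L)
    sequence_pair(pat, txt, id = id, max_length = max_length)
  })
}

#' Write sequence pairs in seqpair format
#'
#' @param path Output file.
#' @param pairs List of [sequence_pair()] objects.
#' @param comment Optional comment string written as a leading `#` line.
#' @export
write_pairs <- function(path, pairs, comment = NULL) {
  body <- unlist(lapply(pairs, function(p) c(paste0(">", p$pattern),
                                             paste0("<", p$text))))
  if (is.null(body)) body <- character(0)
  if (!is.null(comment)) body <- c(paste0("# ", comment), body)
  writeLines(body, path)
  invisible(path)
}

#' Write an alignment result table
#'
#' One tab-separated line per pair: id, status (`OK`/`FAIL`), score
#' (empty when failed), CIGAR string (empty when failed); trailing
#' newline; UTF-8.
#'
#' @param path Output file.
#' @param results Data frame from [run_batch()] or a list of `alignment`
#'   objects.
#' @export
write_alignments <- function(path, results) {
  if (!is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, function(a) data.frame(
      id = a$pair_id, status = if (a$success) "OK" else "FAIL",
      score = a$score, cigar = a$cigar, stringsAsFactors = FALSE)))
  }
  lines <- sprintf("%s\t%s\t%s\t%s", results$id, results$status,
                   ifelse(results$status == "OK", as.character(results$score),
                          ""),
                   ifelse(results$status == "OK", results$cigar, ""))
  con <- file(path, open = "wb") # fixed newline convention across platforms
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read an alignment result table back
#'
#' Inverse of [write_alignments()]: recovers id, status, score and CIGAR
#' exactly.
#'
#' @param path File written by [write_alignments()].
#' @return Data frame with columns `id`, `status`, `score`, `cigar`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(data.frame(id = character(0), status = character(0),
                      score = integer(0), cigar = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad))
    stop_input(sprintf("line %d: expected 4 tab-separated fields", bad[1L]))
  field <- function(i) vapply(parts, function(p)
    if (length(p) >= i) p[[i]] else "", character(1))
  data.frame(id = field(1L), status = field(2L),
             score = suppressWarnings(as.integer(field(3L))),
             cigar = field(4L), stringsAsFactors = FALSE)
}
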