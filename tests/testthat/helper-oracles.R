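# Shared fixtures and tiny independent oracles, built in code.

# pure-R memoized recursion over the linear-gap cost recurrence; used to
# pin the compiled reference oracle itself on small inputs
nw_cost_memo_r <- function(pattern, text, pen = linear_penalties()) {
  pc <- strsplit(pattern, "")[[1]]
  tc <- strsplit(text, "")[[1]]
  m <- length(pc); n <- length(tc)
  memo <- matrix(NA_integer_, m + 1L, n + 1L)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    v <- if (i == 0L) j * pen$indel
    else if (j == 0L) i * pen$indel
    else min(rec(i - 1L, j - 1L) +
               (if (pc[i] == tc[j]) pen$match else pen$mismatch),
             rec(i - 1L, j) + pen$indel,
             rec(i, j - 1L) + pen$indel)
    memo[i + 1L, j + 1L] <<- v
    v
  }
  rec(m, n)
}

# global affine-gap alignment cost via Biostrings (score negation);
# requires nonempty sequences
biostrings_cost <- function(pattern, text, pen) {
  mat <- matrix(-pen$mismatch, 4, 4,
                dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(mat) <- -pen$match
  if (inherits(pen, "affine_penalties")) {
    go <- pen$gap_open; ge <- pen$gap_extend
  } else {
    go <- 0; ge <- pen$indel
  }
  aln <- Biostrings::pairwiseAlignment(pattern, text, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = go, gapExtension = ge)
  -as.integer(aln@score)
}

# deterministic fuzz pairs at mixed lengths/error rates
fuzz_pairs <- function(n, lengths, errors, seed) {
  grid <- expand.grid(len = lengths, err = errors)
  out <- vector("list", n)
  idx <- 1L
  g <- 0L
  while (idx <= n) {
    row <- grid[(g %% nrow(grid)) + 1L, ]
    take <- min(n - idx + 1L, 25L)
    ps <- generate_pairs(take, row$len, row$err, seed = seed + g)
    for (p in ps) { out[[idx]] <- p; idx <- idx + 1L }
    g <- g + 1L
  }
  out
}

expect_valid_alignment <- function(aln, pair, penalties) {
  expect_true(aln$success)
  expect_true(cigar_validate(aln$cigar, nchar(pair$pattern),
                             nchar(pair$text)))
  expect_identical(cigar_score(aln$cigar, penalties), aln$score)
}
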