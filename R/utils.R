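# Internal helpers shared across modules.

#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#'   readDNAStringSet writeXStringSet BStringSet subseq
#' @importFrom stats median rnorm rbinom rnbinom rgamma rmultinom p.adjust
#'   pnorm phyper binom.test var complete.cases
#' @importFrom utils write.table read.table combn packageVersion
NULL

# Dirichlet sampler via independent gammas.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

# Reverse-complement of plain character vectors (vectorised).
revcompChar <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

# Extract the plus-strand genomic substring [start, end] (1-based, clamped).
# Returns "" when the clamped interval is empty.
chromSubseq <- function(chromSeq, start, end) {
  n <- length(chromSeq)
  start <- max(1L, start)
  end <- min(n, end)
  if (start > end) return(DNAString(""))
  subseq(chromSeq, start, end)
}

# Transcript-strand sequence of [start, end] plus-genome interval.
transcriptSeq <- function(chromSeq, start, end, strand) {
  s <- chromSubseq(chromSeq, start, end)
  if (strand == "-") s <- reverseComplement(s)
  s
}

# Deterministic TSV writer used for all pipeline outputs.
writeTsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) df[[j]] <- vapply(df[[j]], function(v) paste(v, collapse = ","), "")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
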