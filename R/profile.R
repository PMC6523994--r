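# Nucleotide-composition profiles around PAC representative positions,
# oriented on the transcript strand.

#' Extract transcript-strand windows around cleavage sites
#'
#' For every PAC (optionally restricted to one region label), the
#' transcript-strand genomic sequence covering relative positions
#' `-upstream` .. `+downstream` around the representative cleavage base
#' (index 0 = the last transcribed base) is extracted; on the minus strand
#' the window is reverse complemented. Positions outside the chromosome
#' are masked with `.` rather than dropped, so all windows have equal
#' width.
#'
#' @param pacs a [PACSet-class] (annotated if `region` is used).
#' @param genome a named [Biostrings::DNAStringSet].
#' @param region optional region label filter (e.g. `"3UTR"`).
#' @param upstream,downstream window extent in nt (defaults 300 and 99,
#'   i.e. a 400-nt window).
#' @return A [Biostrings::DNAStringSet] of windows (masked bases as `.`),
#'   with an attached `offsets` attribute giving the relative coordinate
#'   of the first column.
#' @export
extractWindows <- function(pacs, genome, region = NULL,
                           upstream = 300L, downstream = 99L) {
  if (!is.null(region)) pacs <- pacs[pacRegions(pacs) == region, ]
  rr <- rowRanges(pacs)
  if (!length(rr)) stop("no PACs to profile")
  chrom <- as.character(seqnames(rr))
  minus <- as.character(strand(rr)) == "-"
  p <- representativePositions(pacs)
  ws <- ifelse(minus, p - downstream, p - upstream)
  we <- ifelse(minus, p + upstream, p + downstream)
  out <- character(length(rr))
  for (cn in unique(chrom)) {
    ci <- match(cn, names(genome))
    if (is.na(ci)) stopf("genome is missing chromosome '%s'", cn)
    len <- width(genome)[ci]
    sel <- which(chrom == cn)
    cs <- pmax(ws[sel], 1L); ce <- pmin(we[sel], len)
    exr <- extractAt(genome[[ci]], IRanges(cs, ce))
    mcols(exr) <- NULL
    ex <- as.character(exr)
    padL <- strrep(".", cs - ws[sel])
    padR <- strrep(".", we[sel] - ce)
    s <- paste0(padL, ex, padR)
    mm <- minus[sel]
    if (any(mm)) {
      rc <- as.character(reverseComplement(DNAStringSet(chartr(".", "-", s[mm]))))
      s[mm] <- chartr("-", ".", rc)
    }
    out[sel] <- s
  }
  res <- DNAStringSet(out)
  names(res) <- rownames(pacs)
  attr(res, "offsets") <- -as.integer(upstream)
  res
}

#' Per-position base composition of cleavage-site windows
#'
#' Computes, at every relative position, the fraction of A, C, G and T
#' over the windows whose sequence covers that position (masked `.` bases
#' are excluded from the denominator, not counted as zeros). At plant
#' poly(A) sites this recovers the A-rich near-upstream element (AATAAA
#' class) ~25 nt upstream of 3'UTR cleavage sites.
#'
#' @param windows result of [extractWindows()].
#' @param region region label recorded in the output (informational).
#' @return A data frame in long format: `region`, `position` (relative to
#'   the cleavage base at 0), `base`, `fraction`, `n` (covering windows).
#'   Positions covered by no window carry `NA` fractions.
#' @export
baseComposition <- function(windows, region = "all") {
  if (!length(windows)) stop("no windows supplied")
  off <- attr(windows, "offsets")
  if (is.null(off)) off <- 0L
  cm <- Biostrings::consensusMatrix(windows)
  bases <- c("A", "C", "G", "T")
  present <- intersect(bases, rownames(cm))
  cnt <- matrix(0, 4, ncol(cm), dimnames = list(bases, NULL))
  cnt[present, ] <- cm[present, , drop = FALSE]
  n <- colSums(cnt)
  frac <- sweep(cnt, 2L, ifelse(n > 0, n, NA_real_), "/")
  data.frame(
    region = region,
    position = rep(seq_len(ncol(cnt)) + off - 1L, each = 4L),
    base = rep(bases, ncol(cnt)),
    fraction = as.numeric(frac),
    n = rep(as.integer(n), each = 4L))
}
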