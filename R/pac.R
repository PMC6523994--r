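# PAS/PAC construction: exact-coordinate grouping of tags, internal-priming
# artifact removal, single-linkage clustering, support filtering and
# representative-site selection.

#' @importFrom Biostrings extractAt letterFrequency
#' @importFrom IRanges IntegerList
NULL

#' Group mapped tags into poly(A) sites
#'
#' Tags sharing (chromosome, strand, cleavage position) collapse into one
#' PAS; counts are tallied per sample. Total PAS counts equal the number
#' of input tags.
#'
#' @param tags a width-1 [GenomicRanges::GRanges] of mapped tags with a
#'   `sample_id` metadata column (factor levels define the sample set).
#' @param samples sample names for the count matrix columns; defaults to
#'   the levels of `sample_id`.
#' @return A [PASSet-class].
#' @export
buildPAS <- function(tags, samples = NULL) {
  smp <- tags$sample_id
  if (is.null(smp)) stop("tags must carry a 'sample_id' metadata column")
  if (is.null(samples))
    samples <- if (is.factor(smp)) levels(smp) else sort(unique(as.character(smp)))
  if (!length(tags)) {
    se <- SummarizedExperiment(
      assays = list(counts = matrix(0L, 0, length(samples),
                                    dimnames = list(NULL, samples))),
      rowRanges = GRanges())
    return(new("PASSet", se))
  }
  chrom <- as.character(seqnames(tags))
  str <- as.character(strand(tags))
  pos <- start(tags)
  key <- paste(chrom, str, pos, sep = "\r")
  tab <- table(factor(key), factor(as.character(smp), levels = samples))
  keys <- rownames(tab)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  df <- data.frame(chrom = parts[, 1], strand = parts[, 2],
                   pos = as.integer(parts[, 3]))
  ord <- order(df$chrom, df$strand, df$pos)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(NULL, colnames(tab)))[ord, , drop = FALSE]
  df <- df[ord, ]
  rr <- GRanges(df$chrom, IRanges(df$pos, width = 1L), strand = df$strand)
  se <- SummarizedExperiment(assays = list(counts = counts), rowRanges = rr)
  new("PASSet", se)
}

# longest run of A in a character vector of sequences
.maxRunA <- function(s) {
  vapply(gregexpr("A+", s), function(m) {
    if (m[1] == -1L) 0L else max(attr(m, "match.length"))
  }, integer(1))
}

# transcript-strand sequence of the `win`-nt window immediately downstream
# (3') of each cleavage position; truncated at chromosome ends
.downstreamWindows <- function(pas, genome, win) {
  rr <- rowRanges(pas)
  chrom <- as.character(seqnames(rr))
  minus <- as.character(strand(rr)) == "-"
  p <- start(rr)
  ws <- ifelse(minus, p - win, p + 1L)
  we <- ifelse(minus, p - 1L, p + win)
  out <- character(length(rr))
  for (cn in unique(chrom)) {
    ci <- match(cn, names(genome))
    if (is.na(ci)) stopf("genome is missing chromosome '%s'", cn)
    len <- width(genome)[ci]
    sel <- which(chrom == cn)
    cs <- pmax(ws[sel], 1L)
    ce <- pmin(we[sel], len)
    if (any(ws[sel] < 1L | we[sel] > len))
      warning("internal-priming window extends past the end of '", cn,
              "'; missing bases treated as non-A")
    keepable <- cs <= ce
    seqs <- rep("", length(sel))
    if (any(keepable)) {
      ex <- extractAt(genome[[ci]], IRanges(cs[keepable], ce[keepable]))
      mcols(ex) <- NULL
      mm <- minus[sel][keepable]
      ex[mm] <- reverseComplement(ex[mm])
      seqs[keepable] <- as.character(ex)
    }
    out[sel] <- seqs
  }
  out
}

#' Remove internal-priming artifacts
#'
#' A PAS is flagged as an internal-priming artifact - oligo-dT priming on
#' a genomic A-rich tract rather than a true poly(A) tail - when the
#' transcript-strand genomic window immediately downstream of its cleavage
#' position contains at least `ipMaxA` adenosines or a run of at least
#' `ipMaxRunA` consecutive adenosines. Both retained and removed sets are
#' returned for audit.
#'
#' @param pas a [PASSet-class].
#' @param genome a named [Biostrings::DNAStringSet].
#' @param params a [PacParams-class].
#' @return A list with `retained` and `removed`, both [PASSet-class].
#' @export
filterInternalPriming <- function(pas, genome, params = pacParams()) {
  validObject(params)
  if (!nrow(pas)) return(list(retained = pas, removed = pas))
  win <- .downstreamWindows(pas, genome, params@ipWindow)
  nA <- as.integer(letterFrequency(DNAStringSet(win), "A"))
  runA <- .maxRunA(win)
  artifact <- nA >= params@ipMaxA | runA >= params@ipMaxRunA
  list(retained = pas[!artifact, ], removed = pas[artifact, ])
}

#' Select the representative position of a cluster
#'
#' The member PAS with the highest total read count across samples; ties
#' are broken by the 3'-most position in transcription direction (largest
#' coordinate on "+", smallest on "-").
#'
#' @param positions member PAS positions.
#' @param totals total read count of each member across samples.
#' @param strand `"+"` or `"-"`.
#' @return the representative position (integer scalar).
#' @export
pickRepresentative <- function(positions, totals, strand) {
  best <- which(totals == max(totals))
  if (length(best) > 1L) {
    best <- if (strand == "+") best[which.max(positions[best])]
            else best[which.min(positions[best])]
  }
  positions[best]
}

#' Cluster poly(A) sites into PACs
#'
#' Single-linkage chaining per chromosome and strand: consecutive PAS whose
#' positional gap is at most `clusterGap` nt (inclusive) join the same PAC;
#' maximal such groups are returned with summed per-sample counts, the
#' member positions, and the representative position.
#'
#' @param pas a [PASSet-class].
#' @param params a [PacParams-class].
#' @return A [PACSet-class]; row ranges span the member sites.
#' @export
clusterPAS <- function(pas, params = pacParams()) {
  validObject(params)
  counts <- assay(pas, "counts")
  if (!nrow(pas)) {
    rr0 <- GRanges()
    mcols(rr0) <- DataFrame(pac_id = character(0),
                            representative = integer(0),
                            n_sites = integer(0),
                            member_sites = IntegerList())
    se <- SummarizedExperiment(assays = list(counts = counts), rowRanges = rr0)
    return(new("PACSet", se))
  }
  rr <- rowRanges(pas)
  chrom <- as.character(seqnames(rr))
  str <- as.character(strand(rr))
  pos <- start(rr)
  ord <- order(chrom, str, pos)
  grpKey <- paste(chrom, str)[ord]
  newGroup <- c(TRUE, grpKey[-1] != grpKey[-length(grpKey)] |
                      diff(pos[ord]) > params@clusterGap)
  cl <- cumsum(newGroup)
  idxByCl <- split(ord, cl)

  n <- length(idxByCl)
  outChrom <- character(n); outStrand <- character(n)
  outStart <- integer(n); outEnd <- integer(n)
  rep_ <- integer(n); nSites <- integer(n)
  members <- vector("list", n)
  cmat <- matrix(0L, n, ncol(counts), dimnames = list(NULL, colnames(counts)))
  for (i in seq_len(n)) {
    m <- idxByCl[[i]]
    outChrom[i] <- chrom[m[1]]; outStrand[i] <- str[m[1]]
    pmem <- pos[m]
    outStart[i] <- min(pmem); outEnd[i] <- max(pmem)
    sub <- counts[m, , drop = FALSE]
    cmat[i, ] <- as.integer(colSums(sub))
    rep_[i] <- pickRepresentative(pmem, rowSums(sub), outStrand[i])
    nSites[i] <- length(m)
    members[[i]] <- sort(pmem)
  }
  ordOut <- order(outChrom, outStart, outStrand)
  rrOut <- GRanges(outChrom[ordOut], IRanges(outStart[ordOut], outEnd[ordOut]),
                   strand = outStrand[ordOut])
  mcols(rrOut) <- DataFrame(pac_id = sprintf("PAC%05d", seq_len(n)),
                            representative = rep_[ordOut],
                            n_sites = nSites[ordOut],
                            member_sites = IntegerList(members[ordOut]))
  se <- SummarizedExperiment(assays = list(counts = cmat[ordOut, , drop = FALSE]),
                             rowRanges = rrOut)
  names(se) <- mcols(rrOut)$pac_id
  new("PACSet", se)
}

#' Drop weakly supported PACs
#'
#' A PAC is retained iff its read count summed over all samples is at
#' least `minPacReads` (default 10; clusters with fewer reads are
#' discarded).
#'
#' @param pacs a [PACSet-class].
#' @param params a [PacParams-class].
#' @return the retained [PACSet-class].
#' @export
filterPACs <- function(pacs, params = pacParams()) {
  validObject(params)
  keep <- rowSums(assay(pacs, "counts")) >= params@minPacReads
  pacs[keep, ]
}
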