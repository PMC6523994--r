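# Shared in-code fixtures: tiny genomes, tag sets and count containers.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(SummarizedExperiment)
  library(S4Vectors)
  library(IRanges)
})

# deterministic pseudo-random chromosome without long A/T runs
randomChrom <- function(n, seed = 1) {
  set.seed(seed)
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  r <- rle(b)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in which(r$lengths >= 6 & r$values %in% c("A", "T")))
    b[seq(starts[i] + 5L, ends[i], by = 6L)] <- "C"
  paste(b, collapse = "")
}

# genome with a given plus-strand string as chr1
toyGenome <- function(seqs) {
  g <- DNAStringSet(seqs)
  if (is.null(names(seqs))) names(g) <- paste0("chr", seq_along(seqs))
  g
}

# width-1 tag GRanges from vectors
makeTags <- function(pos, strand = "+", sample = "s1", chrom = "chr1",
                     samples = NULL) {
  n <- length(pos)
  pos <- rep_len(pos, n); strand <- rep_len(strand, n)
  sample <- rep_len(sample, n); chrom <- rep_len(chrom, n)
  if (is.null(samples)) samples <- sort(unique(sample))
  GRanges(chrom, IRanges(pos, width = 1), strand = strand,
          sample_id = factor(sample, levels = samples))
}

# PASSet straight from positions and a count matrix
makePAS <- function(pos, counts, strand = "+", chrom = "chr1") {
  counts <- as.matrix(counts)
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = GRanges(chrom, IRanges(pos, width = 1), strand = strand))
  new("PASSet", se)
}

# FASTQ reads with explicit quality integers
makeReads <- function(seqs, quals) {
  qs <- vapply(quals, function(q) rawToChar(as.raw(q + 33L)), "")
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(Biostrings::BStringSet(qs)))
}

# minimal GFF3-style gene model GRanges (single-exon gene unless cds is a
# list of intervals)
makeGeneGr <- function(geneId, chrom, strand, gStart, gEnd,
                       utr5 = NULL, cds = NULL, utr3 = NULL) {
  rows <- list(
    GRanges(chrom, IRanges(gStart, gEnd), strand = strand, type = "gene",
            ID = geneId, Parent = NA_character_),
    GRanges(chrom, IRanges(gStart, gEnd), strand = strand, type = "mRNA",
            ID = paste0(geneId, ".1"), Parent = geneId))
  addFeat <- function(iv, type) {
    if (is.null(iv)) return(NULL)
    iv <- matrix(iv, ncol = 2, byrow = TRUE)
    lapply(seq_len(nrow(iv)), function(k)
      GRanges(chrom, IRanges(iv[k, 1], iv[k, 2]), strand = strand, type = type,
              ID = paste0(geneId, ".", type, k), Parent = paste0(geneId, ".1")))
  }
  rows <- c(rows, addFeat(utr5, "five_prime_UTR"), addFeat(cds, "CDS"),
            addFeat(utr3, "three_prime_UTR"))
  out <- do.call(c, rows[!vapply(rows, is.null, TRUE)])
  names(out) <- NULL
  out
}
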