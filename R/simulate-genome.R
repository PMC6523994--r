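# Toy-genome generator: gene loci with 5'UTR/CDS/3'UTR architecture,
# planted poly(A) sites with per-condition usage, AATAAA-like elements
# upstream of each site, and A-rich internal-priming decoy tracts.

# Fixed gene geometry (transcript coordinates, nt). Genes are intronless;
# intron-region assignment is exercised with hand-built annotations.
.GENE_UTR5 <- 100L
.GENE_CDS <- 300L
.GENE_UTR3 <- 200L
.GENE_LEN <- .GENE_UTR5 + .GENE_CDS + .GENE_UTR3
.GENE_SPACER <- 400L
# transcript-coordinate slots where sites may be planted, spaced so that
# neighbouring sites form distinct PACs under the default 24-nt gap
.SLOTS_UTR3 <- c(425L, 500L, 575L)
.SLOTS_CDS <- c(250L, 330L)
.SLOTS_DOWN <- 850L          # 250 nt past the gene end: beyond the 120-nt
                             # 3'UTR extension, hence truth region "downstream"
.DECOY_T <- 150L             # transcript start of the 10-A decoy tract

# genome position of transcript coordinate t for a gene on [gStart, gEnd]
.txToGenome <- function(t, gStart, gEnd, strand) {
  if (strand == "+") gStart + t - 1L else gEnd - t + 1L
}

# write `chars` (transcript strand, 5'->3' from transcript coordinate tStart)
# into the plus-strand base vector
.plantTranscript <- function(bases, gStart, gEnd, strand, tStart, chars) {
  n <- length(chars)
  if (strand == "+") {
    pos <- gStart + tStart - 1L + seq_len(n) - 1L
    bases[pos] <- chars
  } else {
    pos <- gEnd - (tStart + n - 1L) + 1L + seq_len(n) - 1L
    comp <- c(A = "T", C = "G", G = "C", T = "A")[rev(chars)]
    bases[pos] <- comp
  }
  bases
}

# break every run of >= 6 A or >= 6 T so that planted decoys are the only
# A-rich tracts the internal-priming filter can fire on
.scrubHomopolymers <- function(bases) {
  r <- rle(bases)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$lengths >= 6L & r$values %in% c("A", "T"))) {
    sub <- if (r$values[i] == "A") "C" else "G"
    brk <- seq(starts[i] + 5L, ends[i], by = 6L)
    bases[brk] <- sub
  }
  bases
}

#' Generate a toy genome, gene annotation and poly(A)-site ground truth
#'
#' Lays out `nGenes` intronless genes (100 nt 5'UTR, 300 nt CDS, 200 nt
#' 3'UTR) on alternating strands of a single chromosome, separated by
#' intergenic spacers. Each gene receives 1-3 poly(A) sites drawn from the
#' configured region mix; switching genes receive exactly two 3'UTR sites
#' 150 nt apart with deterministic flipped usage. An AATAAA element is
#' planted ~25 nt upstream of every site (so composition profiles have
#' recoverable signal), the two bases at and before each cleavage site are
#' fixed non-A (so the cleavage coordinate is recoverable after oligo-dT
#' trimming), and a 10-A decoy tract is planted in the CDS of a random
#' `decoyFraction` of genes. Background runs of 6 or more A (or T) are
#' broken so the decoys are the only tracts the internal-priming filter
#' should fire on.
#'
#' @param config a [SimConfig-class].
#' @return A list with elements `genome` (a named
#'   [Biostrings::DNAStringSet]), `features` (a GFF3-style
#'   [GenomicRanges::GRanges] with `type`, `ID` and `Parent` columns) and
#'   `truth` (a `SimTruth` list with `genes`, `sites` and `decoys` data
#'   frames; site usage proportions appear as one `usage_<condition>`
#'   column per condition).
#' @examples
#' sim <- generateGenome(simConfig(nGenes = 10, seed = 1))
#' sim$truth$genes[1:3, ]
#' @export
generateGenome <- function(config) {
  validObject(config)
  set.seed(config@seed)
  nG <- config@nGenes
  required <- .GENE_SPACER + nG * (.GENE_LEN + .GENE_SPACER)
  L <- if (config@genomeLength > 0L) config@genomeLength else required
  if (L < required)
    stopf("genomeLength %d too small to host %d genes (need >= %d nt)",
          L, nG, required)

  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  bases <- .scrubHomopolymers(bases)

  gStart <- .GENE_SPACER + (seq_len(nG) - 1L) * (.GENE_LEN + .GENE_SPACER) + 1L
  gEnd <- gStart + .GENE_LEN - 1L
  strand <- rep(c("+", "-"), length.out = nG)
  geneId <- sprintf("gene%04d", seq_len(nG))

  switchGenes <- if (config@nSwitchGenes > 0L)
    sort(sample(seq_len(nG), config@nSwitchGenes)) else integer(0)
  isSwitch <- seq_len(nG) %in% switchGenes

  hasDecoy <- as.logical(rbinom(nG, 1L, config@decoyFraction))

  nCond <- length(config@conditions)
  siteRows <- vector("list", nG)
  decoyRows <- vector("list", nG)

  for (i in seq_len(nG)) {
    if (isSwitch[i]) {
      tSites <- c(.SLOTS_UTR3[1], .SLOTS_UTR3[3])   # 150 nt apart, both 3'UTR
      region <- c("utr3", "utr3")
      usage <- matrix(rep(config@switchUsage, nCond), nrow = 2)
      if (nCond >= 2L) usage[, 2] <- rev(config@switchUsage)
    } else {
      nS <- sample(seq(config@nSitesRange[1], config@nSitesRange[2]), 1L)
      free <- list(utr3 = .SLOTS_UTR3, cds = .SLOTS_CDS, downstream = .SLOTS_DOWN)
      want <- sample(names(config@siteRegionMix), nS, replace = TRUE,
                     prob = config@siteRegionMix)
      tSites <- integer(0); region <- character(0)
      for (w in want) {
        if (!length(free[[w]])) w <- "utr3"
        if (!length(free[[w]])) next
        tSites <- c(tSites, free[[w]][1]); region <- c(region, w)
        free[[w]] <- free[[w]][-1]
      }
      ord <- order(tSites)
      tSites <- tSites[ord]; region <- region[ord]
      u <- rdirichlet1(rep(config@usageConcentration, length(tSites)))
      usage <- matrix(rep(u, nCond), ncol = nCond)
    }

    for (k in seq_along(tSites)) {
      t <- tSites[k]
      bases <- .plantTranscript(bases, gStart[i], gEnd[i], strand[i],
                                t - 30L, strsplit("AATAAA", "")[[1]])
      # non-A at and just before the cleavage base: keeps the oligo-dT trim
      # from eating genuine 3'-end sequence
      bases <- .plantTranscript(bases, gStart[i], gEnd[i], strand[i],
                                t - 1L, c("G", "C"))
    }

    if (hasDecoy[i]) {
      bases <- .plantTranscript(bases, gStart[i], gEnd[i], strand[i],
                                .DECOY_T, rep("A", 10L))
      cleavT <- .DECOY_T - 1L
      tractPos <- sort(vapply(.DECOY_T:(.DECOY_T + 9L), .txToGenome,
                              integer(1), gStart[i], gEnd[i], strand[i]))
      decoyRows[[i]] <- data.frame(
        gene_id = geneId[i], chrom = "chr1", strand = strand[i],
        tract_start = tractPos[1], tract_end = tractPos[10],
        cleavage_pos = .txToGenome(cleavT, gStart[i], gEnd[i], strand[i]))
    }

    pos <- vapply(tSites, .txToGenome, integer(1), gStart[i], gEnd[i], strand[i])
    df <- data.frame(
      gene_id = geneId[i],
      site_id = sprintf("%s.s%d", geneId[i], seq_along(tSites)),
      chrom = "chr1", strand = strand[i], position = pos,
      t = tSites, region = region)
    for (ci in seq_len(nCond))
      df[[paste0("usage_", config@conditions[ci])]] <- usage[, ci]
    siteRows[[i]] <- df
  }

  # cap A content in the 10-nt downstream window of every true site so the
  # internal-priming filter cannot misfire on genuine cleavage sites
  sites <- do.call(rbind, siteRows)
  for (r in seq_len(nrow(sites))) {
    gi <- match(sites$gene_id[r], geneId)
    win <- sites$t[r] + 1:10
    posWin <- vapply(win, .txToGenome, integer(1), gStart[gi], gEnd[gi], strand[gi])
    txBase <- bases[posWin]
    if (strand[gi] == "-") txBase <- c(A = "T", C = "G", G = "C", T = "A")[txBase]
    isA <- txBase == "A"
    if (sum(isA) >= 6L) {
      kill <- which(isA)[seq(2L, sum(isA), by = 2L)]
      for (kk in kill)    # window index kk sits at transcript position t + kk
        bases <- .plantTranscript(bases, gStart[gi], gEnd[gi], strand[gi],
                                  sites$t[r] + kk, "C")
    }
  }
  rownames(sites) <- NULL

  genome <- DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- "chr1"

  features <- .buildGeneFeatures(geneId, gStart, gEnd, strand)
  truth <- structure(list(
    genes = data.frame(gene_id = geneId, chrom = "chr1", strand = strand,
                       start = gStart, end = gEnd, switch = isSwitch,
                       has_decoy = hasDecoy),
    sites = sites,
    decoys = do.call(rbind, decoyRows),
    conditions = config@conditions
  ), class = c("SimTruth", "list"))

  list(genome = genome, features = features, truth = truth)
}

# GFF3-style GRanges for the fixed intronless gene architecture
.buildGeneFeatures <- function(geneId, gStart, gEnd, strand) {
  nG <- length(geneId)
  one <- function(i) {
    s <- gStart[i]; e <- gEnd[i]; st <- strand[i]
    tx <- function(t1, t2) {     # transcript interval -> genomic interval
      p <- sort(c(.txToGenome(t1, s, e, st), .txToGenome(t2, s, e, st)))
      IRanges(p[1], p[2])
    }
    GRanges("chr1",
      c(IRanges(s, e), IRanges(s, e),
        tx(1L, .GENE_UTR5),
        tx(.GENE_UTR5 + 1L, .GENE_UTR5 + .GENE_CDS),
        tx(.GENE_UTR5 + .GENE_CDS + 1L, .GENE_LEN)),
      strand = st,
      type = c("gene", "mRNA", "five_prime_UTR", "CDS", "three_prime_UTR"),
      phase = c(NA, NA, NA, 0L, NA),
      ID = c(geneId[i], paste0(geneId[i], ".1"), paste0(geneId[i], ".1.utr5"),
             paste0(geneId[i], ".1.cds"), paste0(geneId[i], ".1.utr3")),
      Parent = c(NA, geneId[i], paste0(geneId[i], ".1"),
                 paste0(geneId[i], ".1"), paste0(geneId[i], ".1")))
  }
  out <- do.call(c, lapply(seq_len(nG), one))
  names(out) <- NULL
  out
}

#' @export
print.SimTruth <- function(x, ...) {
  cat("SimTruth:", nrow(x$genes), "genes,", nrow(x$sites), "poly(A) sites,",
      if (is.null(x$decoys)) 0L else nrow(x$decoys), "decoy tracts,",
      sum(x$genes$switch), "switching genes\n")
  invisible(x)
}
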