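# Tag-level simulation: negative-binomial expression, multinomial site
# usage, cleavage-position jitter, internal-priming artifacts, and FASTQ /
# BED emission.

#' Simulate poly(A) tags for every sample
#'
#' For each gene and replicate the total tag count is drawn from a negative
#' binomial with the configured mean and dispersion, allocated to the
#' gene's poly(A) sites by a multinomial over the condition's usage
#' proportions, and scattered around the true cleavage position with
#' Gaussian jitter (rounded, clamped to the gene locus plus flanks). A
#' fraction `internalPrimingRate` of tags is re-assigned to a random decoy
#' tract, with the cleavage position set to the base immediately 5' of the
#' tract on the transcript strand.
#'
#' @param sim the list returned by [generateGenome()].
#' @param config the same [SimConfig-class] used to generate the genome.
#' @return A list with `tags` (a width-1 [GenomicRanges::GRanges] at the
#'   cleavage base of every tag, with `sample_id`, `condition`,
#'   `replicate`, `gene_id`, `site_id` and `artifact` metadata columns) and
#'   `samples` (the sample sheet: sample, condition, replicate).
#' @examples
#' cfg <- simConfig(nGenes = 10, expressionMean = 20, seed = 1)
#' sim <- generateGenome(cfg)
#' tg <- simulateTags(sim, cfg)
#' table(tg$tags$sample_id)
#' @export
simulateTags <- function(sim, config) {
  validObject(config)
  set.seed(config@seed + 1L)
  truth <- sim$truth
  genesDf <- truth$genes
  sites <- truth$sites
  decoys <- truth$decoys

  samples <- expand.grid(replicate = seq_len(config@replicatesPerCondition),
                         condition = config@conditions,
                         stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_rep%d", samples$condition, samples$replicate)
  samples <- samples[, c("sample", "condition", "replicate")]

  size <- if (config@expressionDispersion > 0) 1 / config@expressionDispersion else Inf
  out <- vector("list", nrow(genesDf) * nrow(samples))
  k <- 0L
  for (i in seq_len(nrow(genesDf))) {
    gid <- genesDf$gene_id[i]
    gs <- sites[sites$gene_id == gid, , drop = FALSE]
    lo <- genesDf$start[i] - 300L
    hi <- genesDf$end[i] + 300L
    for (j in seq_len(nrow(samples))) {
      n <- if (is.finite(size))
        rnbinom(1L, mu = config@expressionMean, size = size)
      else rpois(1L, config@expressionMean)
      if (n == 0L) next
      usage <- gs[[paste0("usage_", samples$condition[j])]]
      alloc <- as.integer(rmultinom(1L, n, usage))
      siteIdx <- rep(seq_len(nrow(gs)), alloc)
      pos <- gs$position[siteIdx]
      if (config@cleavageJitterSD > 0) {
        pos <- pos + as.integer(round(rnorm(length(pos), 0, config@cleavageJitterSD)))
        pos <- pmin(pmax(pos, lo), hi)
      }
      k <- k + 1L
      out[[k]] <- data.frame(chrom = gs$chrom[siteIdx], pos = pos,
                             strand = gs$strand[siteIdx],
                             sample = samples$sample[j],
                             condition = samples$condition[j],
                             replicate = samples$replicate[j],
                             gene_id = gid, site_id = gs$site_id[siteIdx],
                             stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out[seq_len(k)])
  df$artifact <- FALSE

  if (config@internalPrimingRate > 0) {
    if (is.null(decoys) || nrow(decoys) == 0L) {
      warning("internalPrimingRate > 0 but no decoy tracts planted; ",
              "no artifact tags generated")
    } else {
      hit <- as.logical(rbinom(nrow(df), 1L, config@internalPrimingRate))
      pick <- sample(seq_len(nrow(decoys)), sum(hit), replace = TRUE)
      df$pos[hit] <- decoys$cleavage_pos[pick]
      df$strand[hit] <- decoys$strand[pick]
      df$chrom[hit] <- decoys$chrom[pick]
      df$gene_id[hit] <- decoys$gene_id[pick]
      df$site_id[hit] <- "ip_artifact"
      df$artifact[hit] <- TRUE
    }
  }

  tags <- GRanges(df$chrom, IRanges(df$pos, width = 1L), strand = df$strand,
                  sample_id = factor(df$sample, levels = samples$sample),
                  condition = df$condition, replicate = df$replicate,
                  gene_id = df$gene_id, site_id = df$site_id,
                  artifact = df$artifact)
  names(tags) <- sprintf("tag%07d", seq_along(tags))
  list(tags = tags, samples = samples)
}

#' Write simulated tags as per-sample FASTQ files
#'
#' Reads are emitted as sequenced from the oligo-dT end: a poly(T) prefix
#' (the reverse-complemented start of the poly(A) tail, length drawn from
#' `polyTRange`) followed by the reverse complement of the transcript-strand
#' genomic sequence ending at the cleavage base. A configurable fraction of
#' reads lacks the poly(T) prefix and a configurable fraction carries
#' uniformly low base qualities; both exercise the preprocessing filters.
#'
#' @param tagSim the list returned by [simulateTags()].
#' @param genome the simulated genome ([Biostrings::DNAStringSet]).
#' @param config the [SimConfig-class] in use.
#' @param dir output directory (created if missing).
#' @return Invisibly, a data frame with one row per sample: `sample`,
#'   `file`, `n_reads`.
#' @export
emitFastq <- function(tagSim, genome, config, dir) {
  validObject(config)
  set.seed(config@seed + 2L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tags <- tagSim$tags
  chromLen <- width(genome)[match(as.character(seqnames(tags)), names(genome))]

  polyT <- sample(seq(config@polyTRange[1], config@polyTRange[2]),
                  length(tags), replace = TRUE)
  tagLen <- config@readLength - polyT
  noPrefix <- as.logical(rbinom(length(tags), 1L, config@noPolyTFraction))
  lowQ <- as.logical(rbinom(length(tags), 1L, config@lowQualityFraction))

  p <- start(tags)
  minus <- as.character(strand(tags)) == "-"
  winStart <- ifelse(minus, p, p - tagLen + 1L)
  winEnd <- ifelse(minus, p + tagLen - 1L, p)
  clampedStart <- pmax(winStart, 1L)
  clampedEnd <- pmin(winEnd, chromLen)
  if (any(clampedStart != winStart | clampedEnd != winEnd))
    warning("some reads truncated at chromosome boundaries")

  manifest <- data.frame(sample = levels(tags$sample_id), file = NA_character_,
                         n_reads = 0L)
  for (s in seq_len(nrow(manifest))) {
    smp <- manifest$sample[s]
    sel <- which(as.character(tags$sample_id) == smp)
    path <- file.path(dir, paste0(smp, ".fastq"))
    if (!length(sel)) {
      file.create(path)
      manifest$file[s] <- path
      next
    }
    seqs <- vector("list", length(sel))
    chromIdx <- match(as.character(seqnames(tags))[sel], names(genome))
    v <- IRanges(clampedStart[sel], clampedEnd[sel])
    u <- Biostrings::extractAt(genome[[1]], v)   # single-chromosome genomes
    mcols(u) <- NULL
    if (length(unique(chromIdx)) > 1L) {
      u <- DNAStringSet(lapply(seq_along(sel), function(ii)
        chromSubseq(genome[[chromIdx[ii]]], clampedStart[sel[ii]], clampedEnd[sel[ii]])))
    }
    u[minus[sel]] <- reverseComplement(u[minus[sel]])  # transcript strand
    readGenomic <- reverseComplement(u)
    prefix <- ifelse(noPrefix[sel], "", strrep("T", polyT[sel]))
    readSeq <- DNAStringSet(paste0(prefix, as.character(readGenomic)))
    names(readSeq) <- names(tags)[sel]
    qual <- BStringSet(strrep(ifelse(lowQ[sel], "#", "I"), width(readSeq)))
    writeXStringSet(readSeq, path, format = "fastq", qualities = qual)
    manifest$file[s] <- path
    manifest$n_reads[s] <- length(sel)
  }
  invisible(manifest)
}

#' Write simulated tags as per-sample BED6 files
#'
#' One BED line per tag: a single-base 0-based half-open interval at the
#' cleavage position with the strand column set. This bypasses read-level
#' preprocessing for pipelines starting from pre-mapped tag 3' ends.
#'
#' @inheritParams emitFastq
#' @return Invisibly, a data frame with `sample`, `file`, `n_tags`.
#' @seealso [readTagBed()] for the inverse operation.
#' @export
emitBed <- function(tagSim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tags <- tagSim$tags
  manifest <- data.frame(sample = levels(tags$sample_id), file = NA_character_,
                         n_tags = 0L)
  for (s in seq_len(nrow(manifest))) {
    smp <- manifest$sample[s]
    sel <- as.character(tags$sample_id) == smp
    gr <- granges(tags[sel])
    mcols(gr)$name <- names(tags)[sel]
    mcols(gr)$score <- 0L
    names(gr) <- NULL
    path <- file.path(dir, paste0(smp, ".bed"))
    rtracklayer::export(gr, path, format = "BED")
    manifest$file[s] <- path
    manifest$n_tags[s] <- sum(sel)
  }
  invisible(manifest)
}

#' @importFrom GenomicRanges granges
NULL
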