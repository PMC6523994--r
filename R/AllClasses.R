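#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<- Rle
#' @importFrom GenomicRanges GRanges seqnames strand start end width
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges
#'   rowData colData rowData<- colData<-
NULL

#' Simulation configuration for synthetic PAT-Seq data
#'
#' Holds every tunable of the synthetic-data generator: toy-genome layout,
#' per-gene poly(A)-site architecture, negative-binomial expression model,
#' Dirichlet site-usage model, planted switching genes, internal-priming
#' decoys, and read-structure parameters.
#'
#' @slot nGenes number of genes in the toy genome.
#' @slot genomeLength total genome length in nt; `0` sizes the genome
#'   automatically from the gene layout.
#' @slot nSitesRange integer range (min, max) of poly(A) sites per gene.
#' @slot siteRegionMix named proportions over `utr3`, `cds`, `downstream`
#'   governing where non-switch sites are planted.
#' @slot expressionMean negative-binomial mean tag count per gene and
#'   replicate.
#' @slot expressionDispersion negative-binomial dispersion (`1/size`).
#' @slot usageConcentration Dirichlet concentration for per-gene site-usage
#'   proportions (shared across conditions for non-switch genes).
#' @slot nSwitchGenes number of genes with a planted usage flip.
#' @slot switchUsage usage vector of the two switch sites in the first
#'   condition; reversed in the second.
#' @slot conditions condition labels.
#' @slot replicatesPerCondition replicates per condition.
#' @slot cleavageJitterSD SD (nt) of Gaussian scatter applied to cleavage
#'   positions.
#' @slot internalPrimingRate fraction of tags re-assigned to A-rich decoy
#'   tracts (internal-priming artifacts).
#' @slot decoyFraction fraction of genes carrying a planted >=8-A decoy
#'   tract in their CDS.
#' @slot readLength sequenced read length in nt.
#' @slot polyTRange range (min, max) of the leading poly(T) run length.
#' @slot noPolyTFraction fraction of reads emitted without the poly(T)
#'   prefix (exercises the oligo-dT discard rule).
#' @slot lowQualityFraction fraction of reads emitted with uniformly low
#'   base qualities (exercises quality filtering).
#' @slot seed integer seed; a fixed seed makes every emitted artifact
#'   byte-identical across runs.
#' @seealso [simConfig()], [generateGenome()], [simulateTags()]
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nGenes = "integer",
    genomeLength = "integer",
    nSitesRange = "integer",
    siteRegionMix = "numeric",
    expressionMean = "numeric",
    expressionDispersion = "numeric",
    usageConcentration = "numeric",
    nSwitchGenes = "integer",
    switchUsage = "numeric",
    conditions = "character",
    replicatesPerCondition = "integer",
    cleavageJitterSD = "numeric",
    internalPrimingRate = "numeric",
    decoyFraction = "numeric",
    readLength = "integer",
    polyTRange = "integer",
    noPolyTFraction = "numeric",
    lowQualityFraction = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (length(object@nSitesRange) != 2L || any(object@nSitesRange < 1L) ||
      object@nSitesRange[1] > object@nSitesRange[2])
    msg <- c(msg, "nSitesRange must be an increasing pair of positive integers")
  if (abs(sum(object@siteRegionMix) - 1) > 1e-8 || any(object@siteRegionMix < 0))
    msg <- c(msg, "siteRegionMix proportions must be non-negative and sum to 1")
  if (!identical(sort(names(object@siteRegionMix)), c("cds", "downstream", "utr3")))
    msg <- c(msg, "siteRegionMix must be named utr3, cds, downstream")
  if (object@expressionMean <= 0) msg <- c(msg, "expressionMean must be positive")
  if (object@expressionDispersion < 0) msg <- c(msg, "expressionDispersion must be >= 0")
  if (object@usageConcentration <= 0) msg <- c(msg, "usageConcentration must be positive")
  if (object@nSwitchGenes < 0L) msg <- c(msg, "nSwitchGenes must be >= 0")
  if (object@nSwitchGenes > object@nGenes) msg <- c(msg, "nSwitchGenes exceeds nGenes")
  if (length(object@switchUsage) != 2L || abs(sum(object@switchUsage) - 1) > 1e-8)
    msg <- c(msg, "switchUsage must be two proportions summing to 1")
  if (length(object@conditions) < 1L) msg <- c(msg, "at least one condition required")
  if (anyDuplicated(object@conditions)) msg <- c(msg, "condition labels must be unique")
  if (object@replicatesPerCondition < 1L) msg <- c(msg, "replicatesPerCondition must be >= 1")
  if (object@cleavageJitterSD < 0) msg <- c(msg, "cleavageJitterSD must be >= 0")
  if (object@internalPrimingRate < 0 || object@internalPrimingRate > 1)
    msg <- c(msg, "internalPrimingRate must be in [0, 1]")
  if (object@decoyFraction < 0 || object@decoyFraction > 1)
    msg <- c(msg, "decoyFraction must be in [0, 1]")
  if (object@readLength < 1L) msg <- c(msg, "readLength must be positive")
  if (length(object@polyTRange) != 2L || any(object@polyTRange < 1L) ||
      object@polyTRange[1] > object@polyTRange[2])
    msg <- c(msg, "polyTRange must be an increasing pair of positive integers")
  if (object@polyTRange[2] >= object@readLength)
    msg <- c(msg, "polyTRange must leave room for genomic sequence within readLength")
  if (object@noPolyTFraction < 0 || object@noPolyTFraction > 1)
    msg <- c(msg, "noPolyTFraction must be in [0, 1]")
  if (object@lowQualityFraction < 0 || object@lowQualityFraction > 1)
    msg <- c(msg, "lowQualityFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults encode the standard simulated study: 200 genes in a toy genome,
#' negative-binomial expression with mean 200 and dispersion 0.1, two
#' conditions with three replicates each, 10 planted switching genes whose
#' two 3'UTR sites flip usage 0.8/0.2 to 0.2/0.8, cleavage scatter of 2 nt,
#' and A-rich decoy tracts in half of the gene bodies.
#'
#' @param nGenes,genomeLength,nSitesRange,siteRegionMix,expressionMean,expressionDispersion,usageConcentration,nSwitchGenes,switchUsage,conditions,replicatesPerCondition,cleavageJitterSD,internalPrimingRate,decoyFraction,readLength,polyTRange,noPolyTFraction,lowQualityFraction,seed
#'   see the corresponding [SimConfig-class] slots.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 20, seed = 1)
#' cfg
#' @export
simConfig <- function(nGenes = 200L,
                      genomeLength = 0L,
                      nSitesRange = c(1L, 3L),
                      siteRegionMix = c(utr3 = 0.8, cds = 0.1, downstream = 0.1),
                      expressionMean = 200,
                      expressionDispersion = 0.1,
                      usageConcentration = 5,
                      nSwitchGenes = 10L,
                      switchUsage = c(0.8, 0.2),
                      conditions = c("A", "B"),
                      replicatesPerCondition = 3L,
                      cleavageJitterSD = 2,
                      internalPrimingRate = 0,
                      decoyFraction = 0.5,
                      readLength = 50L,
                      polyTRange = c(8L, 20L),
                      noPolyTFraction = 0,
                      lowQualityFraction = 0,
                      seed = 1L) {
  new("SimConfig",
    nGenes = as.integer(nGenes),
    genomeLength = as.integer(genomeLength),
    nSitesRange = as.integer(nSitesRange),
    siteRegionMix = siteRegionMix[c("utr3", "cds", "downstream")],
    expressionMean = expressionMean,
    expressionDispersion = expressionDispersion,
    usageConcentration = usageConcentration,
    nSwitchGenes = as.integer(nSwitchGenes),
    switchUsage = switchUsage,
    conditions = conditions,
    replicatesPerCondition = as.integer(replicatesPerCondition),
    cleavageJitterSD = cleavageJitterSD,
    internalPrimingRate = internalPrimingRate,
    decoyFraction = decoyFraction,
    readLength = as.integer(readLength),
    polyTRange = as.integer(polyTRange),
    noPolyTFraction = noPolyTFraction,
    lowQualityFraction = lowQualityFraction,
    seed = as.integer(seed)
  )
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes,",
      length(object@conditions), "conditions x",
      object@replicatesPerCondition, "replicates\n")
  cat("  expression: NB(mean=", object@expressionMean,
      ", dispersion=", object@expressionDispersion, ")\n", sep = "")
  cat("  switch genes:", object@nSwitchGenes,
      sprintf("(usage %.2f/%.2f flipped)", object@switchUsage[1], object@switchUsage[2]), "\n")
  cat("  jitter sd:", object@cleavageJitterSD, "nt;",
      "internal priming:", object@internalPrimingRate, "\n")
  cat("  seed:", object@seed, "\n")
})

#' Poly(A) sites with per-sample tag counts
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are
#' single-nucleotide cleavage coordinates (poly(A) sites, PAS) and whose
#' `counts` assay holds per-sample tag counts. Built from mapped tags with
#' [buildPAS()].
#'
#' @exportClass PASSet
setClass("PASSet", contains = "RangedSummarizedExperiment")

setValidity("PASSet", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
  }
  if (length(object) && any(width(rowRanges(object)) != 1L))
    msg <- c(msg, "PAS ranges must have width 1 (a single cleavage base)")
  if (length(object) && any(as.character(strand(rowRanges(object))) == "*"))
    msg <- c(msg, "PAS must be stranded")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PASSet", function(object) {
  cat("PASSet with", nrow(object), "poly(A) sites,",
      ncol(object), "samples,",
      sum(assay(object, "counts")), "tags\n")
})

#' Poly(A)-site clusters (PACs) with per-sample counts
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are PACs:
#' maximal single-linkage groups of PAS whose consecutive positional gaps do
#' not exceed the cluster gap. Row ranges span the member sites; `rowData`
#' carries the representative position (the most abundant member site), the
#' member positions, and - after [assignRegions()] - the gene and region
#' assignment.
#'
#' @exportClass PACSet
setClass("PACSet", contains = "RangedSummarizedExperiment")

setValidity("PACSet", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  rd <- rowData(object)
  for (col in c("representative", "n_sites"))
    if (!col %in% colnames(rd)) msg <- c(msg, paste0("rowData column '", col, "' is required"))
  if (length(object) && "representative" %in% colnames(rd)) {
    bad <- rd$representative < start(rowRanges(object)) |
           rd$representative > end(rowRanges(object))
    if (any(bad)) msg <- c(msg, "representative positions must lie within cluster spans")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PACSet", function(object) {
  cat("PACSet with", nrow(object), "poly(A)-site clusters,",
      ncol(object), "samples,",
      sum(assay(object, "counts")), "tags\n")
  if ("region" %in% colnames(rowData(object))) {
    tab <- table(rowData(object)$region)
    cat("  regions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' Gene models with extended 3'UTRs
#'
#' Parsed gene annotation used for PAC assignment: gene spans plus CDS,
#' 5'UTR, 3'UTR, 3'UTRs extended downstream in transcription direction
#' (default 120 nt, truncated at the next same-strand gene), and derived
#' introns. All coordinates are 1-based GRanges.
#'
#' @slot genes [GenomicRanges::GRanges] of gene spans, named by gene id.
#' @slot cds,utr5,utr3,utr3ext,introns [GenomicRanges::GRangesList] of
#'   feature intervals per gene.
#' @slot extension 3'UTR extension length (nt) used to build `utr3ext`.
#' @exportClass GeneModels
setClass("GeneModels",
  representation(
    genes = "GRanges",
    cds = "GRangesList",
    utr5 = "GRangesList",
    utr3 = "GRangesList",
    utr3ext = "GRangesList",
    introns = "GRangesList",
    extension = "integer"
  )
)

setValidity("GeneModels", function(object) {
  msg <- character(0)
  if (is.null(names(object@genes)) || anyDuplicated(names(object@genes)))
    msg <- c(msg, "genes must be uniquely named by gene id")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneModels", function(object) {
  cat("GeneModels with", length(object@genes), "genes on",
      length(unique(as.character(seqnames(object@genes)))), "sequence(s);",
      "3'UTR extension", object@extension, "nt\n")
})

#' @describeIn GeneModels-class gene spans as a named GRanges
#' @param object a `GeneModels` object
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))

#' @rdname GeneModels-class
#' @export
setMethod("genes", "GeneModels", function(object) object@genes)

#' Accessors for PAC properties
#'
#' `representativePositions()` returns the representative cleavage position
#' of each PAC (the member PAS with the highest total count, ties broken by
#' the 3'-most position in transcription direction). `pacRegions()` and
#' `pacGenes()` return the region label and gene assignment added by
#' [assignRegions()]; `memberSites()` the member PAS positions.
#'
#' @param object a [PACSet-class]
#' @return an integer vector (positions), character vector (regions/genes),
#'   or [IRanges::IntegerList] (member sites), parallel to the rows.
#' @name pac-accessors
NULL

#' @rdname pac-accessors
#' @export
setGeneric("representativePositions", function(object) standardGeneric("representativePositions"))

#' @rdname pac-accessors
#' @export
setMethod("representativePositions", "PACSet", function(object) rowData(object)$representative)

#' @rdname pac-accessors
#' @export
setGeneric("memberSites", function(object) standardGeneric("memberSites"))

#' @rdname pac-accessors
#' @export
setMethod("memberSites", "PACSet", function(object) rowData(object)$member_sites)

#' @rdname pac-accessors
#' @export
setGeneric("pacRegions", function(object) standardGeneric("pacRegions"))

#' @rdname pac-accessors
#' @export
setMethod("pacRegions", "PACSet", function(object) {
  if (!"region" %in% colnames(rowData(object)))
    stop("PACSet has no region annotation; run assignRegions() first")
  rowData(object)$region
})

#' @rdname pac-accessors
#' @export
setGeneric("pacGenes", function(object) standardGeneric("pacGenes"))

#' @rdname pac-accessors
#' @export
setMethod("pacGenes", "PACSet", function(object) {
  if (!"gene_id" %in% colnames(rowData(object)))
    stop("PACSet has no gene annotation; run assignRegions() first")
  rowData(object)$gene_id
})
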