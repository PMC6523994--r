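# Parameter bundles for the read-processing and PAC-building stages.

#' Read preprocessing parameters
#'
#' Defaults mirror a standard PAT-Seq raw-data stage: FASTX-style quality
#' filtering (at least `minPercentAtQuality`% of bases at Phred quality >=
#' `minQuality`, boundary inclusive), removal of the leading oligo-dT
#' (poly(T)) run of at least `minPolyTRun` nt with one mismatch tolerated
#' after 10 consecutive T, and discarding of trimmed tags shorter than
#' `minTrimmedLength` nt.
#'
#' @slot minQuality Phred threshold (default 10).
#' @slot minPercentAtQuality percent of bases that must meet it (default 50).
#' @slot minTrimmedLength minimum tag length after trimming (default 20).
#' @slot minPolyTRun minimum leading poly(T) run to accept as oligo-dT
#'   evidence (default 8).
#' @exportClass PreprocessParams
setClass("PreprocessParams",
  representation(minQuality = "integer", minPercentAtQuality = "numeric",
                 minTrimmedLength = "integer", minPolyTRun = "integer"))

setValidity("PreprocessParams", function(object) {
  msg <- character(0)
  if (object@minPercentAtQuality < 0 || object@minPercentAtQuality > 100)
    msg <- c(msg, "minPercentAtQuality must be in [0, 100]")
  if (object@minTrimmedLength < 1L) msg <- c(msg, "minTrimmedLength must be positive")
  if (object@minPolyTRun < 1L) msg <- c(msg, "minPolyTRun must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname PreprocessParams-class
#' @param minQuality,minPercentAtQuality,minTrimmedLength,minPolyTRun see slots.
#' @return a validated `PreprocessParams` object.
#' @export
preprocessParams <- function(minQuality = 10L, minPercentAtQuality = 50,
                             minTrimmedLength = 20L, minPolyTRun = 8L) {
  new("PreprocessParams", minQuality = as.integer(minQuality),
      minPercentAtQuality = minPercentAtQuality,
      minTrimmedLength = as.integer(minTrimmedLength),
      minPolyTRun = as.integer(minPolyTRun))
}

setMethod("show", "PreprocessParams", function(object) {
  cat("PreprocessParams: Q>=", object@minQuality, " in >=",
      object@minPercentAtQuality, "% of bases; min tag ",
      object@minTrimmedLength, " nt; min poly(T) run ",
      object@minPolyTRun, " nt\n", sep = "")
})

#' PAC-building parameters
#'
#' `clusterGap` is the maximum positional gap (nt, inclusive) between
#' consecutive PAS merged into one PAC; `minPacReads` the minimum total
#' read support across all samples for a PAC to be retained. The
#' internal-priming rule removes a PAS when the `ipWindow`-nt
#' transcript-strand sequence immediately downstream of the cleavage site
#' contains at least `ipMaxA` adenosines or a run of at least `ipMaxRunA`
#' consecutive adenosines.
#'
#' @slot clusterGap nt (default 24).
#' @slot minPacReads count (default 10).
#' @slot ipWindow nt (default 10).
#' @slot ipMaxA count (default 7).
#' @slot ipMaxRunA count (default 6).
#' @exportClass PacParams
setClass("PacParams",
  representation(clusterGap = "integer", minPacReads = "integer",
                 ipWindow = "integer", ipMaxA = "integer", ipMaxRunA = "integer"))

setValidity("PacParams", function(object) {
  vals <- c(object@clusterGap, object@minPacReads, object@ipWindow,
            object@ipMaxA, object@ipMaxRunA)
  if (any(vals < 1L)) "all PacParams fields must be positive" else TRUE
})

#' @rdname PacParams-class
#' @param clusterGap,minPacReads,ipWindow,ipMaxA,ipMaxRunA see slots.
#' @return a validated `PacParams` object.
#' @export
pacParams <- function(clusterGap = 24L, minPacReads = 10L, ipWindow = 10L,
                      ipMaxA = 7L, ipMaxRunA = 6L) {
  new("PacParams", clusterGap = as.integer(clusterGap),
      minPacReads = as.integer(minPacReads), ipWindow = as.integer(ipWindow),
      ipMaxA = as.integer(ipMaxA), ipMaxRunA = as.integer(ipMaxRunA))
}

setMethod("show", "PacParams", function(object) {
  cat("PacParams: gap<=", object@clusterGap, " nt; support>=",
      object@minPacReads, " reads; IP window ", object@ipWindow,
      " nt (>=", object@ipMaxA, " A or run>=", object@ipMaxRunA, ")\n", sep = "")
})

#' Poly(A)-site switching criteria thresholds
#'
#' The five switching criteria for a PAC pair (PA1, PA2) between two sample
#' groups: (1) one of PA1/PA2 has count >= `minCountEachSample` in each
#' group; (2) at least one has total count across all samples >=
#' `minTotalCount`; (3) PA1/PA2 >= `minRatio` in one group and PA2/PA1 >=
#' `minRatio` in the other; (4) |PA1 - PA2| > `minAbsDiff` (strictly) in
#' both groups; (5) at least one of the pair is a significant DE-PAC
#' (disabled with `requireDePac = FALSE`).
#'
#' @slot minCountEachSample default 5.
#' @slot minTotalCount default 20.
#' @slot minRatio default 2.
#' @slot minAbsDiff default 5 (strict inequality).
#' @slot requireDePac default TRUE.
#' @exportClass SwitchParams
setClass("SwitchParams",
  representation(minCountEachSample = "numeric", minTotalCount = "numeric",
                 minRatio = "numeric", minAbsDiff = "numeric",
                 requireDePac = "logical"))

setValidity("SwitchParams", function(object) {
  vals <- c(object@minCountEachSample, object@minTotalCount, object@minRatio,
            object@minAbsDiff)
  if (any(vals <= 0)) "all SwitchParams thresholds must be positive" else TRUE
})

#' @rdname SwitchParams-class
#' @param minCountEachSample,minTotalCount,minRatio,minAbsDiff,requireDePac see slots.
#' @return a validated `SwitchParams` object.
#' @export
switchParams <- function(minCountEachSample = 5, minTotalCount = 20,
                         minRatio = 2, minAbsDiff = 5, requireDePac = TRUE) {
  new("SwitchParams", minCountEachSample = minCountEachSample,
      minTotalCount = minTotalCount, minRatio = minRatio,
      minAbsDiff = minAbsDiff, requireDePac = requireDePac)
}

setMethod("show", "SwitchParams", function(object) {
  cat("SwitchParams: count>=", object@minCountEachSample,
      " per group; total>=", object@minTotalCount, "; ratio>=",
      object@minRatio, " reciprocal; |diff|>", object@minAbsDiff,
      "; DE-PAC required: ", object@requireDePac, "\n", sep = "")
})
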