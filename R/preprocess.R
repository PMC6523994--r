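# Read-level preprocessing: quality filter, oligo-dT trimming, exact tag
# mapping, and import of pre-mapped tag BED files.

#' @importFrom Biostrings readQualityScaledDNAStringSet quality PDict
#'   matchPDict QualityScaledDNAStringSet
#' @importFrom IRanges elementNROWS
NULL

.readFastq <- function(x) {
  if (is.character(x)) {
    tryCatch(suppressWarnings(readQualityScaledDNAStringSet(x)),
             error = function(e) stopf("malformed FASTQ '%s': %s",
                                       x, conditionMessage(e)))
  } else x
}

#' Quality-filter PAT reads
#'
#' Retains a read iff at least `minPercentAtQuality` percent of its bases
#' have Phred quality at or above `minQuality` (boundary inclusive) -
#' FASTX-Toolkit quality-filter semantics.
#'
#' @param reads a FASTQ path (Phred+33) or a
#'   [Biostrings::QualityScaledDNAStringSet].
#' @param params a [PreprocessParams-class].
#' @return A list with `reads` (the retained
#'   `QualityScaledDNAStringSet`) and `counts` (named integer vector:
#'   `input`, `retained`, `discarded`).
#' @export
qualityFilter <- function(reads, params = preprocessParams()) {
  validObject(params)
  reads <- .readFastq(reads)
  if (!length(reads))
    return(list(reads = reads, counts = c(input = 0L, retained = 0L, discarded = 0L)))
  q <- as(quality(reads), "IntegerList")
  frac <- sum(q >= params@minQuality) / elementNROWS(q)
  keep <- frac * 100 >= params@minPercentAtQuality
  list(reads = reads[keep],
       counts = c(input = length(reads), retained = sum(keep),
                  discarded = sum(!keep)))
}

# leading poly(T) run length, with one mismatch tolerated after 10
# consecutive T (the anchored base of the oligo-dT primer)
.polyTPrefix <- function(s) {
  m <- regexpr("^T+", s)
  t1 <- ifelse(m > 0L, attr(m, "match.length"), 0L)
  prim <- t1
  elig <- t1 >= 10L & nchar(s) > t1 + 1L
  if (any(elig)) {
    rest <- substring(s[elig], t1[elig] + 2L)
    m2 <- regexpr("^T+", rest)
    t2 <- ifelse(m2 > 0L, attr(m2, "match.length"), 0L)
    prim[elig] <- ifelse(t2 > 0L, t1[elig] + 1L + t2, t1[elig])
  }
  list(run = t1, prefix = prim)
}

#' Trim the oligo-dT prefix from PAT reads
#'
#' Removes the leading poly(T) run (the read-through of the poly(A) tail).
#' Reads whose leading run is shorter than `minPolyTRun` carry no oligo-dT
#' evidence and are discarded; trimmed tags shorter than
#' `minTrimmedLength` are discarded as well.
#'
#' @param reads a [Biostrings::DNAStringSet] (or quality-scaled variant) of
#'   quality-filtered reads.
#' @param params a [PreprocessParams-class].
#' @return A list with `tags` (a named [Biostrings::DNAStringSet] of
#'   trimmed tags) and `counts` (`input`, `trimmed`, `no_oligo_dt`,
#'   `too_short`).
#' @export
trimTags <- function(reads, params = preprocessParams()) {
  validObject(params)
  s <- as.character(reads)
  if (!length(s))
    return(list(tags = DNAStringSet(),
                counts = c(input = 0L, trimmed = 0L, no_oligo_dt = 0L,
                           too_short = 0L)))
  pt <- .polyTPrefix(s)
  noOligo <- pt$run < params@minPolyTRun
  trimmed <- substring(s, pt$prefix + 1L)
  short <- !noOligo & nchar(trimmed) < params@minTrimmedLength
  keep <- !noOligo & !short
  tags <- DNAStringSet(trimmed[keep])
  names(tags) <- names(reads)[keep]
  list(tags = tags,
       counts = c(input = length(s), trimmed = sum(keep),
                  no_oligo_dt = sum(noOligo), too_short = sum(short)))
}

#' Map trimmed tags to a toy genome by exact matching
#'
#' Each tag's reverse complement is searched as an exact substring of the
#' genome in both orientations. A match on the plus strand of the genome
#' (of the tag's reverse complement) places the cleavage site at the
#' 3'-most matched base on "+"; a match of the tag itself places it at the
#' 5'-most genomic base on "-" (the transcript-strand 3' end in both
#' cases). Tags matching no locus, more than one locus, or containing
#' ambiguous bases are discarded and counted.
#'
#' @param tags a named [Biostrings::DNAStringSet] of trimmed tags.
#' @param genome a named [Biostrings::DNAStringSet].
#' @param sampleId sample label stored on the output tags.
#' @return A list with `tags` (width-1 [GenomicRanges::GRanges] at the
#'   cleavage base, metadata column `sample_id`) and `counts` (`input`,
#'   `mapped`, `multimapped`, `unmapped`).
#' @export
mapTags <- function(tags, genome, sampleId = "sample1") {
  s <- as.character(tags)
  empty <- GRanges()
  mcols(empty)$sample_id <- factor(character(0))
  if (!length(s))
    return(list(tags = empty,
                counts = c(input = 0L, mapped = 0L, multimapped = 0L,
                           unmapped = 0L)))
  uu <- unique(s)
  clean <- grepl("^[ACGT]+$", uu)
  nhit <- integer(length(uu))
  hitChrom <- character(length(uu))
  hitStrand <- character(length(uu))
  hitPos <- integer(length(uu))

  if (any(clean)) {
    idx <- which(clean)
    pats <- DNAStringSet(uu[idx])
    rcp <- reverseComplement(pats)
    # one variable-width dictionary per orientation, exact-matched over a
    # trusted band covering the shortest tag and verified over the rest
    tb <- min(width(pats))
    pdPlus <- PDict(rcp, tb.start = 1L, tb.end = tb)   # "+" gene: match ends at cleavage
    pdMinus <- PDict(pats, tb.start = 1L, tb.end = tb) # "-" gene: match starts at cleavage
    for (ci in seq_along(genome)) {
      chromName <- names(genome)[ci]
      mPlus <- matchPDict(pdPlus, genome[[ci]])
      mMinus <- matchPDict(pdMinus, genome[[ci]])
      for (ori in c("+", "-")) {
        m <- if (ori == "+") mPlus else mMinus
        cnt <- elementNROWS(m)
        hit <- which(cnt > 0L)
        if (!length(hit)) next
        nhit[idx[hit]] <- nhit[idx[hit]] + cnt[hit]
        ul <- BiocGenerics::unlist(m)
        pid <- rep(seq_along(cnt), cnt)
        fi <- which(!duplicated(pid))            # first match per pattern
        first <- if (ori == "+") end(ul)[fi] else start(ul)[fi]
        hitChrom[idx[hit]] <- chromName
        hitStrand[idx[hit]] <- ori
        hitPos[idx[hit]] <- first
      }
    }
  }

  uniqHit <- nhit == 1L
  tagU <- match(s, uu)
  mapped <- uniqHit[tagU]
  multim <- nhit[tagU] > 1L
  out <- GRanges(hitChrom[tagU][mapped],
                 IRanges(hitPos[tagU][mapped], width = 1L),
                 strand = hitStrand[tagU][mapped],
                 sample_id = factor(rep(sampleId, sum(mapped))))
  names(out) <- names(tags)[mapped]
  list(tags = out,
       counts = c(input = length(s), mapped = sum(mapped),
                  multimapped = sum(multim), unmapped = sum(!mapped & !multim)))
}

#' Import pre-mapped poly(A) tags from a BED6 file
#'
#' Each line must be a single-base interval (0-based half-open) at the
#' cleavage position with a `+` or `-` strand; this is the inverse of
#' [emitBed()].
#'
#' @param path BED file path.
#' @param sampleId sample label for these tags.
#' @return A width-1 [GenomicRanges::GRanges] with a `sample_id` column.
#' @export
readTagBed <- function(path, sampleId) {
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stopf("malformed BED '%s': %s",
                                           path, conditionMessage(e)))
  if (length(gr) && any(!as.character(strand(gr)) %in% c("+", "-")))
    stopf("BED '%s': strand must be '+' or '-' on every line (line %d)",
          path, which(!as.character(strand(gr)) %in% c("+", "-"))[1])
  if (length(gr) && any(width(gr) != 1L))
    stopf("BED '%s': tag intervals must be single-base (line %d)",
          path, which(width(gr) != 1L)[1])
  out <- granges(gr)
  mcols(out)$sample_id <- factor(rep(sampleId, length(out)))
  if (!is.null(gr$name)) names(out) <- gr$name
  out
}
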