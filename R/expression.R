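# Count normalisation and differential expression: median-of-ratios size
# factors, a moment-based negative-binomial Wald test for replicated
# designs, an exact binomial fallback for unreplicated ones, and generic
# hypergeometric gene-set enrichment.

.countMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) assay(x, "counts") else as.matrix(x)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features of the
#' ratio of its count to the feature's geometric mean across samples;
#' features with a zero in any sample are skipped. Factors are rescaled so
#' their geometric mean is 1.
#'
#' @param x a count matrix (features x samples) or a
#'   SummarizedExperiment with a `counts` assay.
#' @param pseudocount add this to every count before estimation; the
#'   fallback when no feature is nonzero in all samples (default 0).
#' @return named numeric vector of size factors, one per sample.
#' @export
computeSizeFactors <- function(x, pseudocount = 0) {
  counts <- .countMatrix(x) + pseudocount
  if (ncol(counts) == 1L)
    return(structure(1, names = colnames(counts)))
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    stop("no feature has nonzero counts in all samples; ",
         "consider computeSizeFactors(x, pseudocount = 0.5)")
  lg <- log(counts[ok, , drop = FALSE])
  loggeo <- rowMeans(lg)
  lf <- apply(lg - loggeo, 2L, median)
  sf <- exp(lf - mean(lf))
  structure(sf, names = colnames(counts))
}

#' Negative-binomial differential expression between two groups
#'
#' Counts are normalised by median-of-ratios size factors. With replicates
#' in both groups, per-feature dispersions are estimated by method of
#' moments from the pooled within-group variance of normalised counts,
#' shrunk 50/50 toward the global mean dispersion and floored at it
#' (guarding against features whose sample variance is small by chance);
#' a Wald test is then
#' applied to the log2 fold change with the NB variance propagated through
#' the delta method. Without replicates (1 vs 1) an exact two-sided
#' binomial test on the pooled proportion is used instead (lower power).
#' Features whose mean normalised count falls below `minMeanCount` are
#' excluded from testing (independent filtering) and reported with `NA`
#' p-values. Benjamini-Hochberg correction is applied across tested
#' features.
#'
#' @param x count matrix or SummarizedExperiment (`counts` assay).
#' @param groupA,groupB column names (or indices) of the two sample groups.
#' @param alpha adjusted-p significance threshold for the `significant`
#'   flag (genes are conventionally called at 0.01, PACs at 0.05).
#' @param minMeanCount independent-filtering floor on the mean normalised
#'   count (default 1).
#' @param sizeFactors optional precomputed size factors for all columns of
#'   `x`; computed from `x` when `NULL`.
#' @return A [S4Vectors::DataFrame] with one row per feature:
#'   `baseMeanA`, `baseMeanB`, `log2FoldChange`, `dispersion`, `pvalue`,
#'   `padj`, `tested`, `significant`.
#' @export
deTest <- function(x, groupA, groupB, alpha = 0.05, minMeanCount = 1,
                   sizeFactors = NULL) {
  counts <- .countMatrix(x)
  if (is.numeric(groupA)) groupA <- colnames(counts)[groupA]
  if (is.numeric(groupB)) groupB <- colnames(counts)[groupB]
  if (!length(groupA) || !length(groupB))
    stop("both groups must contain at least one sample")
  bad <- setdiff(c(groupA, groupB), colnames(counts))
  if (length(bad))
    stopf("sample(s) not in the count matrix: %s", paste(bad, collapse = ", "))

  if (is.null(sizeFactors)) {
    sizeFactors <- tryCatch(computeSizeFactors(counts[, c(groupA, groupB), drop = FALSE]),
                            error = function(e) computeSizeFactors(
                              counts[, c(groupA, groupB), drop = FALSE],
                              pseudocount = 0.5))
    norm <- sweep(counts[, c(groupA, groupB), drop = FALSE], 2L, sizeFactors, "/")
  } else {
    norm <- sweep(counts[, c(groupA, groupB), drop = FALSE], 2L,
                  sizeFactors[c(groupA, groupB)], "/")
  }
  nA <- length(groupA); nB <- length(groupB)
  matA <- norm[, groupA, drop = FALSE]
  matB <- norm[, groupB, drop = FALSE]
  mA <- rowMeans(matA); mB <- rowMeans(matB)
  baseMean <- rowMeans(norm)
  tested <- baseMean >= minMeanCount

  nFeat <- nrow(counts)
  pval <- rep(NA_real_, nFeat)
  lfc <- rep(NA_real_, nFeat)
  disp <- rep(NA_real_, nFeat)
  pc <- 0.5   # pseudocount stabilising the fold change at low counts

  if (nA >= 2L && nB >= 2L) {
    vA <- apply(matA, 1L, var); vB <- apply(matB, 1L, var)
    vPool <- ((nA - 1L) * vA + (nB - 1L) * vB) / (nA + nB - 2L)
    dRaw <- pmax((vPool - baseMean) / baseMean^2, 1e-8)
    # global dispersion = mean of the raw moment estimates (the median is
    # biased low at few replicates); per-feature estimates are shrunk
    # toward it and floored at it, which keeps the Wald test calibrated
    # when a feature's sample variance is small by chance
    dGlob <- mean(dRaw[tested])
    disp <- pmax(0.5 * dRaw + 0.5 * dGlob, dGlob)
    lfc <- log2((mB + pc) / (mA + pc))
    varA <- (mA + disp * mA^2) / nA
    varB <- (mB + disp * mB^2) / nB
    seLfc <- sqrt(varA / (mA + pc)^2 + varB / (mB + pc)^2) / log(2)
    z <- ifelse(seLfc > 0, lfc / seLfc, 0)
    pval <- 2 * pnorm(-abs(z))
    pval[lfc == 0] <- 1
  } else {
    # no replicates: exact binomial test on the pooled proportion
    sfA <- sum(sizeFactors[groupA]); sfB <- sum(sizeFactors[groupB])
    prop <- sfB / (sfA + sfB)
    a <- rowSums(counts[, groupA, drop = FALSE])
    b <- rowSums(counts[, groupB, drop = FALSE])
    lfc <- log2((mB + pc) / (mA + pc))
    pval <- vapply(seq_len(nFeat), function(i) {
      tot <- a[i] + b[i]
      if (tot == 0) return(1)
      binom.test(b[i], tot, p = prop)$p.value
    }, numeric(1))
    pval[lfc == 0] <- 1
  }

  pval[!tested] <- NA_real_
  padj <- rep(NA_real_, nFeat)
  padj[tested] <- p.adjust(pval[tested], method = "BH")
  res <- DataFrame(feature = if (!is.null(rownames(counts))) rownames(counts)
                             else as.character(seq_len(nFeat)),
                   baseMeanA = mA, baseMeanB = mB,
                   log2FoldChange = lfc, dispersion = disp,
                   pvalue = pval, padj = padj, tested = tested,
                   significant = !is.na(padj) & padj < alpha)
  rownames(res) <- res$feature
  res
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric (Fisher) test per gene set for
#' over-representation of `hits` within `universe`, with
#' Benjamini-Hochberg correction across sets. Sets are intersected with
#' the universe first.
#'
#' @param hits character vector of hit genes (must be a subset of
#'   `universe`).
#' @param universe character vector of all testable genes.
#' @param geneSets named list of character vectors.
#' @param fdr adjusted-p threshold for the `significant` flag (default
#'   0.05).
#' @return A data frame with one row per set: `set`, `set_size`,
#'   `overlap`, `expected`, `pvalue`, `padj`, `significant`, plus the
#'   overlapping genes in `genes`.
#' @export
enrichmentTest <- function(hits, universe, geneSets, fdr = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe is empty")
  hits <- unique(hits)
  if (length(setdiff(hits, universe)))
    stop("hits must be a subset of the universe")
  res <- lapply(names(geneSets), function(nm) {
    set <- intersect(unique(geneSets[[nm]]), universe)
    ov <- intersect(hits, set)
    p <- phyper(length(ov) - 1L, length(set),
                length(universe) - length(set), length(hits),
                lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = length(ov),
               expected = length(hits) * length(set) / length(universe),
               pvalue = p, genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- p.adjust(out$pvalue, method = "BH")
  out$significant <- out$padj < fdr
  out[order(out$pvalue), c("set", "set_size", "overlap", "expected",
                           "pvalue", "padj", "significant", "genes")]
}
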