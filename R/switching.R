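# Poly(A)-site switching detection: genes with >= 2 PACs are screened
# pair-by-pair against five criteria on group-level read counts.

# ratio with the zero conventions: x/0 = Inf for x > 0, 0/0 fails (NaN)
.switchRatio <- function(x, y) {
  if (y > 0) x / y else if (x > 0) Inf else NaN
}

#' Genes eligible for switching analysis
#'
#' @param pacs an annotated [PACSet-class].
#' @return character vector of gene ids with at least two PACs.
#' @export
candidateGenes <- function(pacs) {
  gid <- pacGenes(pacs)
  tab <- table(gid[!is.na(gid)])
  sort(names(tab)[tab >= 2L])
}

#' Evaluate the five switching criteria for one PAC pair
#'
#' Counts are group-level (replicate-summed) read counts of the two PACs
#' in the two compared sample groups. The criteria: (1) one of PA1/PA2 has
#' a count >= `minCountEachSample` in both groups; (2) at least one of
#' PA1/PA2 has a total count across all samples >= `minTotalCount`;
#' (3) PA1/PA2 >= `minRatio` in one group and PA2/PA1 >= `minRatio` in the
#' other (x/0 counts as infinite for x > 0; 0/0 fails); (4) |PA1 - PA2| >
#' `minAbsDiff`, strictly, in both groups; (5) at least one of the pair is
#' a significant DE-PAC for this comparison (skipped when `requireDePac`
#' is `FALSE`). The verdict is the conjunction of all enabled criteria.
#'
#' @param pa1,pa2 numeric length-2 vectors: counts of PA1 and PA2 in
#'   (group A, group B).
#' @param total1,total2 total counts of PA1/PA2 across all samples of the
#'   dataset; default to the pair sums.
#' @param de1,de2 logical: is PA1 / PA2 a significant DE-PAC?
#' @param params a [SwitchParams-class].
#' @return named logical vector `c1`..`c5`, `verdict`.
#' @examples
#' evaluatePair(c(20, 5), c(5, 20), de1 = TRUE, de2 = TRUE)
#' @export
evaluatePair <- function(pa1, pa2, total1 = sum(pa1), total2 = sum(pa2),
                         de1 = FALSE, de2 = FALSE, params = switchParams()) {
  validObject(params)
  if (any(c(pa1, pa2) < 0)) stop("counts must be non-negative")
  c1 <- all(pa1 >= params@minCountEachSample) ||
        all(pa2 >= params@minCountEachSample)
  c2 <- total1 >= params@minTotalCount || total2 >= params@minTotalCount
  c3 <- (isTRUE(.switchRatio(pa1[1], pa2[1]) >= params@minRatio) &&
         isTRUE(.switchRatio(pa2[2], pa1[2]) >= params@minRatio)) ||
        (isTRUE(.switchRatio(pa1[2], pa2[2]) >= params@minRatio) &&
         isTRUE(.switchRatio(pa2[1], pa1[1]) >= params@minRatio))
  c4 <- all(abs(pa1 - pa2) > params@minAbsDiff)
  c5 <- if (params@requireDePac) isTRUE(de1) || isTRUE(de2) else TRUE
  verdict <- c1 && c2 && c3 && c4 && c5
  c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, verdict = verdict)
}

#' Detect poly(A)-site switching genes between two sample groups
#'
#' Every pair of PACs on every candidate gene (>= 2 PACs) is evaluated
#' against the five switching criteria (see [evaluatePair()]). By default
#' "sample" in the criteria means the replicate-summed counts of each
#' group; `perReplicate = TRUE` instead demands that criteria (1), (3) and
#' (4) hold in every single replicate of the respective group.
#'
#' @param pacs an annotated [PACSet-class].
#' @param groupA,groupB sample (column) names of the two groups.
#' @param params a [SwitchParams-class].
#' @param dePac optional result of [deTest()] on the PAC-level counts for
#'   the same comparison (rows named by PAC id); required when
#'   `params@requireDePac` is `TRUE`.
#' @param perReplicate evaluate per replicate instead of on group sums.
#' @return A [S4Vectors::DataFrame] with one row per evaluated pair:
#'   gene id, the two PAC ids, the four group-level counts, flags
#'   `c1`..`c5`, `verdict`, and the usage-shift `direction`
#'   (`proximal_to_distal` or `distal_to_proximal`, from the
#'   representative positions and strand). A gene is switching if any of
#'   its pairs has `verdict == TRUE` (see [switchingGenes()]).
#' @export
detectSwitching <- function(pacs, groupA, groupB, params = switchParams(),
                            dePac = NULL, perReplicate = FALSE) {
  validObject(params)
  counts <- assay(pacs, "counts")
  bad <- setdiff(c(groupA, groupB), colnames(counts))
  if (length(bad))
    stopf("sample group(s) not in the PAC count matrix: %s",
          paste(bad, collapse = ", "))
  if (params@requireDePac && is.null(dePac))
    stop("dePac results are required when requireDePac = TRUE")

  cand <- candidateGenes(pacs)
  empty <- DataFrame(gene_id = character(0), pac1 = character(0),
                     pac2 = character(0), pa1_A = numeric(0), pa1_B = numeric(0),
                     pa2_A = numeric(0), pa2_B = numeric(0),
                     c1 = logical(0), c2 = logical(0), c3 = logical(0),
                     c4 = logical(0), c5 = logical(0), verdict = logical(0),
                     direction = character(0))
  if (!length(cand)) return(empty)

  pacIds <- rowData(pacs)$pac_id
  gid <- pacGenes(pacs)
  gA <- rowSums(counts[, groupA, drop = FALSE])
  gB <- rowSums(counts[, groupB, drop = FALSE])
  totalAll <- rowSums(counts)
  repPos <- representativePositions(pacs)
  strnd <- as.character(strand(rowRanges(pacs)))
  deSig <- if (!is.null(dePac))
    structure(dePac$significant, names = rownames(dePac)) else NULL

  rows <- list()
  for (g in cand) {
    idx <- which(!is.na(gid) & gid == g)
    prs <- combn(idx, 2L)
    for (j in seq_len(ncol(prs))) {
      i1 <- prs[1, j]; i2 <- prs[2, j]
      de1 <- if (is.null(deSig)) FALSE else isTRUE(deSig[pacIds[i1]])
      de2 <- if (is.null(deSig)) FALSE else isTRUE(deSig[pacIds[i2]])
      flags <- evaluatePair(c(gA[i1], gB[i1]), c(gA[i2], gB[i2]),
                            total1 = totalAll[i1], total2 = totalAll[i2],
                            de1 = de1, de2 = de2, params = params)
      if (perReplicate) {
        m1A <- counts[i1, groupA]; m1B <- counts[i1, groupB]
        m2A <- counts[i2, groupA]; m2B <- counts[i2, groupB]
        flags["c1"] <- all(c(m1A, m1B) >= params@minCountEachSample) ||
                       all(c(m2A, m2B) >= params@minCountEachSample)
        rat <- function(x, y) mapply(.switchRatio, x, y)
        flags["c3"] <-
          (all(rat(m1A, m2A) >= params@minRatio) &&
           all(rat(m2B, m1B) >= params@minRatio)) ||
          (all(rat(m1B, m2B) >= params@minRatio) &&
           all(rat(m2A, m1A) >= params@minRatio))
        flags["c3"] <- isTRUE(flags[["c3"]])
        flags["c4"] <- all(abs(c(m1A - m2A, m1B - m2B)) > params@minAbsDiff)
        flags["verdict"] <- all(flags[c("c1", "c2", "c3", "c4", "c5")])
      }
      # proximal = 5'-most PAC in transcription direction
      p1Prox <- if (strnd[i1] == "+") repPos[i1] < repPos[i2]
                else repPos[i1] > repPos[i2]
      px <- if (p1Prox) c(i1, i2) else c(i2, i1)
      shareA <- if (gA[px[1]] + gA[px[2]] > 0)
        gA[px[1]] / (gA[px[1]] + gA[px[2]]) else NA_real_
      shareB <- if (gB[px[1]] + gB[px[2]] > 0)
        gB[px[1]] / (gB[px[1]] + gB[px[2]]) else NA_real_
      direction <- if (is.na(shareA) || is.na(shareB) || shareA == shareB)
        NA_character_
      else if (shareA > shareB) "proximal_to_distal" else "distal_to_proximal"
      rows[[length(rows) + 1L]] <- DataFrame(
        gene_id = g, pac1 = pacIds[i1], pac2 = pacIds[i2],
        pa1_A = gA[i1], pa1_B = gB[i1], pa2_A = gA[i2], pa2_B = gB[i2],
        c1 = flags[["c1"]], c2 = flags[["c2"]], c3 = flags[["c3"]],
        c4 = flags[["c4"]], c5 = flags[["c5"]],
        verdict = flags[["verdict"]], direction = direction)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$gene_id, out$pac1, out$pac2), ]
}

#' @rdname detectSwitching
#' @param events the DataFrame returned by `detectSwitching()`.
#' @return `switchingGenes()`: character vector of genes with at least one
#'   switching pair.
#' @export
switchingGenes <- function(events) {
  sort(unique(events$gene_id[events$verdict]))
}
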