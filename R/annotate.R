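# Gene-model loading (GFF3, 3'UTRs extended downstream) and PAC-to-gene
# region assignment.

#' @importFrom GenomicRanges GRangesList findOverlaps reduce setdiff
#' @importFrom BiocGenerics end<- start<-
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom BiocGenerics unlist
NULL

.firstParent <- function(p) {
  if (is(p, "List") || is.list(p))
    vapply(p, function(x) if (length(x)) x[1] else NA_character_, "")
  else as.character(p)
}

#' Load a gene annotation and extend every 3'UTR
#'
#' Reads a GFF3 annotation (gene / mRNA / CDS / five_prime_UTR /
#' three_prime_UTR features) and derives per-gene feature sets. Every
#' 3'UTR is extended by `extension` nt in transcription direction - poly(A)
#' clusters frequently fall just downstream of annotated gene ends - but
#' never into the next annotated gene on the same strand (the extension is
#' truncated there). Introns are derived as the gene span minus all exonic
#' features.
#'
#' @param x a GFF3 file path or a GFF3-style [GenomicRanges::GRanges] with
#'   `type`, `ID` and `Parent` metadata columns.
#' @param extension 3'UTR extension in nt (default 120).
#' @return A [GeneModels-class].
#' @export
loadAnnotation <- function(x, extension = 120L) {
  gr <- if (is.character(x)) {
    tryCatch(rtracklayer::import(x, format = "gff3"),
             error = function(e) stopf("cannot parse GFF3 '%s': %s",
                                       x, conditionMessage(e)))
  } else x
  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- .firstParent(gr$Parent)

  genes <- gr[type == "gene"]
  if (!length(genes)) stop("annotation contains no gene features")
  geneIds <- as.character(genes$ID)
  names(genes) <- geneIds

  mrna <- type == "mRNA"
  mrnaToGene <- structure(parent[mrna], names = id[mrna])
  orphanM <- mrna & (is.na(parent) | !parent %in% geneIds)
  if (any(orphanM))
    stopf("mRNA feature(s) without a gene parent: %s",
          paste(id[orphanM], collapse = ", "))

  featGene <- function(ftype) {
    sel <- type == ftype
    par <- parent[sel]
    gid <- ifelse(par %in% geneIds, par, unname(mrnaToGene[par]))
    if (any(sel) && any(is.na(gid)))
      stopf("%s feature(s) without resolvable gene parent: %s", ftype,
            paste(ifelse(is.na(id[sel][is.na(gid)]), "<unnamed>",
                         id[sel][is.na(gid)]), collapse = ", "))
    grf <- granges(gr[sel])
    S4Vectors::split(grf, factor(gid, levels = geneIds))
  }

  cds <- featGene("CDS")
  utr5 <- featGene("five_prime_UTR")
  utr3 <- featGene("three_prime_UTR")

  gStrand <- as.character(strand(genes))
  gChrom <- as.character(seqnames(genes))
  utr3ext <- utr3
  for (i in seq_along(geneIds)) {
    u <- utr3ext[[i]]
    if (!length(u)) next
    if (gStrand[i] == "+") {
      k <- which.max(end(u))
      others <- which(gChrom == gChrom[i] & gStrand == "+" &
                      start(genes) > end(u)[k] & geneIds != geneIds[i])
      limit <- if (length(others)) min(start(genes)[others]) - 1L else .Machine$integer.max
      end(u)[k] <- max(end(u)[k], min(end(u)[k] + extension, limit))
    } else {
      k <- which.min(start(u))
      others <- which(gChrom == gChrom[i] & gStrand == "-" &
                      end(genes) < start(u)[k] & geneIds != geneIds[i])
      limit <- if (length(others)) max(end(genes)[others]) + 1L else 1L
      start(u)[k] <- min(start(u)[k], max(start(u)[k] - extension, limit))
    }
    utr3ext[[i]] <- u
  }

  introns <- GRangesList(lapply(seq_along(geneIds), function(i) {
    exonic <- reduce(c(granges(cds[[i]]), granges(utr5[[i]]), granges(utr3[[i]])))
    if (!length(exonic)) return(GRanges())
    GenomicRanges::setdiff(granges(genes[i]), exonic)
  }))
  names(introns) <- geneIds

  new("GeneModels", genes = granges(genes), cds = cds, utr5 = utr5,
      utr3 = utr3, utr3ext = utr3ext, introns = introns,
      extension = as.integer(extension))
}

# 3' end of each gene span in transcription direction
.gene3End <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", end(genes), start(genes))
}

#' Assign PACs to genes and genomic regions
#'
#' Each PAC is tested at its representative position on the matching
#' strand, with precedence extended-3'UTR > CDS > 5'UTR > intron. A PAC
#' hitting no gene feature is intergenic; when overlapping genes compete,
#' the gene whose 3' end is nearest wins. Hits in the extended 3'UTR are
#' labelled `3UTR`.
#'
#' @param pacs a [PACSet-class].
#' @param models a [GeneModels-class].
#' @return the input [PACSet-class] with `gene_id` and `region` added to
#'   its `rowData`.
#' @export
assignRegions <- function(pacs, models) {
  n <- nrow(pacs)
  region <- rep("intergenic", n)
  geneId <- rep(NA_character_, n)
  if (!n) {
    rowData(pacs)$gene_id <- geneId
    rowData(pacs)$region <- region
    return(pacs)
  }
  rr <- rowRanges(pacs)
  repGr <- GRanges(seqnames(rr), IRanges(representativePositions(pacs), width = 1L),
                   strand = strand(rr))
  missing <- !as.character(seqnames(repGr)) %in%
    unique(as.character(seqnames(models@genes)))
  if (any(missing))
    warning(sum(missing), " PAC(s) on chromosomes absent from the annotation; ",
            "labelled intergenic")

  gene3 <- .gene3End(models@genes)
  names(gene3) <- names(models@genes)
  classes <- list(`3UTR` = models@utr3ext, CDS = models@cds,
                  `5UTR` = models@utr5, intron = models@introns)
  assigned <- rep(FALSE, n)
  for (lab in names(classes)) {
    grl <- classes[[lab]]
    fl <- BiocGenerics::unlist(grl, use.names = FALSE)
    if (!length(fl)) next
    flGene <- rep(names(grl), elementNROWS(grl))
    hits <- suppressWarnings(findOverlaps(repGr, fl))
    if (!length(hits)) next
    qh <- queryHits(hits)
    open <- !assigned[qh]
    if (!any(open)) next
    qh <- qh[open]
    gid <- flGene[subjectHits(hits)][open]
    d <- abs(start(repGr)[qh] - gene3[gid])
    ord <- order(qh, d)
    firstOfPac <- !duplicated(qh[ord])
    pick <- ord[firstOfPac]
    geneId[qh[pick]] <- gid[pick]
    region[qh[pick]] <- lab
    assigned[qh[pick]] <- TRUE
  }
  rowData(pacs)$gene_id <- geneId
  rowData(pacs)$region <- region
  pacs
}

#' Collapse PAC counts to gene-level counts
#'
#' Sums the per-sample counts of all PACs assigned to the same gene.
#' Intergenic PACs do not enter the gene matrix; they are returned
#' separately so that total counts are conserved.
#'
#' @param pacs an annotated [PACSet-class] (see [assignRegions()]).
#' @return A list with `genes` (a [SummarizedExperiment::SummarizedExperiment]
#'   of gene x sample counts) and `intergenic` (the intergenic subset of
#'   the input PACs).
#' @export
geneCounts <- function(pacs) {
  gid <- pacGenes(pacs)
  genic <- !is.na(gid)
  counts <- assay(pacs, "counts")
  gm <- rowsum(counts[genic, , drop = FALSE], gid[genic])
  if (is.integer(counts)) storage.mode(gm) <- "integer"
  se <- SummarizedExperiment(
    assays = list(counts = gm),
    rowData = DataFrame(gene_id = rownames(gm)))
  rownames(se) <- rownames(gm)
  list(genes = se, intergenic = pacs[!genic, ])
}
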