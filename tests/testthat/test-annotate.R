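# Gene-model loading, 3'UTR extension and PAC region assignment.

mkPac <- function(pos, strand = "+", chrom = "chr1", total = 20L) {
  clusterPAS(makePAS(pos, matrix(rep(total, length(pos)), length(pos), 1,
                                 dimnames = list(NULL, "A")),
                     strand = strand, chrom = chrom))
}

test_that("3'UTRs are extended 120 nt in transcription direction", {
  gr <- makeGeneGr("g1", "chr1", "+", 1, 1000,
                   utr5 = c(1, 100), cds = c(101, 900), utr3 = c(901, 1000))
  m <- loadAnnotation(gr)
  expect_identical(unname(end(m@utr3ext[["g1"]])), 1120L)
  expect_identical(unname(start(m@utr3ext[["g1"]])), 901L)

  grm <- makeGeneGr("g2", "chr1", "-", 501, 1500,
                    utr5 = c(1401, 1500), cds = c(601, 1400), utr3 = c(501, 600))
  mm <- loadAnnotation(grm)
  expect_identical(unname(start(mm@utr3ext[["g2"]])), 381L)
  expect_identical(unname(end(mm@utr3ext[["g2"]])), 600L)
})

test_that("the extension truncates at the next same-strand gene", {
  gr <- c(makeGeneGr("g1", "chr1", "+", 1, 1000,
                     utr5 = c(1, 100), cds = c(101, 900), utr3 = c(901, 1000)),
          makeGeneGr("g3", "chr1", "+", 1101, 1800,
                     utr5 = c(1101, 1200), cds = c(1201, 1700), utr3 = c(1701, 1800)))
  m <- loadAnnotation(gr)
  expect_identical(unname(end(m@utr3ext[["g1"]])), 1100L)
  # an opposite-strand neighbour does not truncate
  gr2 <- c(makeGeneGr("g1", "chr1", "+", 1, 1000,
                      utr5 = c(1, 100), cds = c(101, 900), utr3 = c(901, 1000)),
           makeGeneGr("g4", "chr1", "-", 1051, 1800,
                      utr5 = c(1701, 1800), cds = c(1101, 1700), utr3 = c(1051, 1100)))
  expect_identical(unname(end(loadAnnotation(gr2)@utr3ext[["g1"]])), 1120L)
})

test_that("introns are derived from the gene span minus exonic features", {
  gr <- makeGeneGr("g1", "chr1", "+", 1, 1000,
                   utr5 = c(1, 100), cds = c(101, 400, 601, 900),
                   utr3 = c(901, 1000))
  m <- loadAnnotation(gr)
  intr <- m@introns[["g1"]]
  expect_identical(unname(start(intr)), 401L)
  expect_identical(unname(end(intr)), 600L)
})

test_that("missing parent relations raise an annotation error", {
  gr <- makeGeneGr("g1", "chr1", "+", 1, 1000,
                   utr5 = c(1, 100), cds = c(101, 900), utr3 = c(901, 1000))
  gr$Parent[gr$type == "CDS"] <- "nonexistent"
  expect_error(loadAnnotation(gr), "parent")
})

test_that("regions are assigned by precedence with the extension honoured", {
  gr <- makeGeneGr("g1", "chr1", "+", 1, 1000,
                   utr5 = c(1, 100), cds = c(101, 400, 601, 900),
                   utr3 = c(901, 1000))
  m <- loadAnnotation(gr)
  lab <- function(pos) {
    p <- assignRegions(mkPac(pos), m)
    list(region = pacRegions(p), gene = pacGenes(p))
  }
  expect_identical(lab(950)$region, "3UTR")
  expect_identical(lab(950)$gene, "g1")
  expect_identical(lab(1050)$region, "3UTR")     # 50 nt past the UTR end
  expect_identical(lab(1120)$region, "3UTR")     # extension boundary
  expect_identical(lab(1130)$region, "intergenic")  # 130 nt past, no gene below
  expect_true(is.na(lab(1130)$gene))
  expect_identical(lab(200)$region, "CDS")
  expect_identical(lab(50)$region, "5UTR")
  expect_identical(lab(500)$region, "intron")
  # strand mismatch -> intergenic
  p <- assignRegions(mkPac(950, strand = "-"), m)
  expect_identical(pacRegions(p), "intergenic")
})

test_that("overlapping genes resolve to the nearest 3' end", {
  gr <- c(makeGeneGr("gA", "chr1", "+", 1, 1000,
                     utr5 = c(1, 100), cds = c(101, 900), utr3 = c(901, 1000)),
          makeGeneGr("gB", "chr1", "+", 801, 2000,
                     utr5 = c(801, 900), cds = c(901, 1900), utr3 = c(1901, 2000)))
  m <- loadAnnotation(gr)
  # 950 is in gA's 3'UTR and gB's CDS: 3UTR precedence -> gA
  p <- assignRegions(mkPac(950), m)
  expect_identical(pacGenes(p), "gA")
  expect_identical(pacRegions(p), "3UTR")
})

test_that("chromosomes absent from the annotation yield intergenic with warning", {
  gr <- makeGeneGr("g1", "chr1", "+", 1, 1000,
                   utr5 = c(1, 100), cds = c(101, 900), utr3 = c(901, 1000))
  m <- loadAnnotation(gr)
  expect_warning(p <- assignRegions(mkPac(500, chrom = "chrX"), m), "absent")
  expect_identical(pacRegions(p), "intergenic")
})

test_that("geneCounts sums PAC counts per gene and conserves totals", {
  gr <- c(makeGeneGr("g1", "chr1", "+", 1, 1000,
                     utr5 = c(1, 100), cds = c(101, 900), utr3 = c(901, 1000)),
          makeGeneGr("g2", "chr1", "+", 2001, 3000,
                     utr5 = c(2001, 2100), cds = c(2101, 2900), utr3 = c(2901, 3000)))
  m <- loadAnnotation(gr)
  counts <- matrix(c(10L, 5L, 12L, 30L), 4, 1, dimnames = list(NULL, "A"))
  pacs <- assignRegions(clusterPAS(makePAS(c(910, 990, 2950, 1500), counts)), m)
  gc <- geneCounts(pacs)
  expect_identical(unname(assay(gc$genes, "counts")["g1", "A"]), 15L)
  expect_identical(unname(assay(gc$genes, "counts")["g2", "A"]), 12L)
  expect_identical(nrow(gc$intergenic), 1L)
  expect_identical(sum(assay(gc$genes, "counts")) + sum(assay(gc$intergenic, "counts")),
                   sum(assay(pacs, "counts")))
})

test_that("all-intergenic input yields an empty gene matrix", {
  gr <- makeGeneGr("g1", "chr1", "+", 1, 1000,
                   utr5 = c(1, 100), cds = c(101, 900), utr3 = c(901, 1000))
  m <- loadAnnotation(gr)
  pacs <- assignRegions(mkPac(5000), m)
  gc <- geneCounts(pacs)
  expect_identical(nrow(gc$genes), 0L)
  expect_identical(nrow(gc$intergenic), 1L)
})

test_that("GFF3 written to disk round-trips through loadAnnotation", {
  sim <- generateGenome(simConfig(nGenes = 8, nSwitchGenes = 2, seed = 2))
  direct <- loadAnnotation(sim$features)
  d <- withr::local_tempdir()
  path <- file.path(d, "ann.gff3")
  rtracklayer::export(sim$features, path, format = "gff3")
  fromFile <- loadAnnotation(path)
  expect_identical(names(genes(fromFile)), names(genes(direct)))
  expect_identical(start(genes(fromFile)), start(genes(direct)))
  expect_identical(unname(start(unlist(fromFile@utr3ext))),
                   unname(start(unlist(direct@utr3ext))))
  expect_identical(unname(end(unlist(fromFile@utr3ext))),
                   unname(end(unlist(direct@utr3ext))))
})

test_that("region labels on jitter-free synthetic data match the planted mix", {
  cfg <- simConfig(nGenes = 200, expressionMean = 60, cleavageJitterSD = 0,
                   internalPrimingRate = 0, nSwitchGenes = 0, seed = 29)
  sim <- generateGenome(cfg)
  tg <- simulateTags(sim, cfg)
  pacs <- assignRegions(filterPACs(clusterPAS(buildPAS(tg$tags))),
                        loadAnnotation(sim$features))
  got <- table(pacRegions(pacs))
  truthTab <- table(sim$truth$sites$region)
  # each PAC is one planted site here; sites too weak for the support
  # filter may drop, so compare proportions with a tolerance
  expect_gt(got[["3UTR"]] / sum(got), 0.7)
  expect_lt(abs(got[["CDS"]] / sum(got) - truthTab[["cds"]] / sum(truthTab)), 0.05)
  expect_lt(abs(got[["intergenic"]] / sum(got) -
                truthTab[["downstream"]] / sum(truthTab)), 0.05)
})
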