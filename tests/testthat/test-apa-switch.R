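# The five-criterion poly(A)-site switching rule.

test_that("evaluatePair reproduces the printed criteria on worked examples", {
  # clean reciprocal switch, both DE
  f <- evaluatePair(c(20, 5), c(5, 20), total1 = 25, total2 = 25,
                    de1 = TRUE, de2 = TRUE)
  expect_true(all(f[c("c1", "c2", "c3", "c4", "c5", "verdict")]))

  # symmetric counts cannot satisfy the reciprocal ratio
  f2 <- evaluatePair(c(10, 10), c(10, 10), de1 = TRUE)
  expect_false(f2[["c3"]]); expect_false(f2[["verdict"]])

  # ratio passes both ways but |PA1 - PA2| = 4 <= 5 fails criterion 4
  f3 <- evaluatePair(c(8, 4), c(4, 8), total1 = 20, total2 = 20, de1 = TRUE)
  expect_true(f3[["c3"]]); expect_false(f3[["c4"]]); expect_false(f3[["verdict"]])

  # criterion 4 is strict: a difference of exactly 5 fails, 6 passes
  expect_false(evaluatePair(c(10, 5), c(5, 10), de1 = TRUE)[["c4"]])
  expect_true(evaluatePair(c(11, 5), c(5, 11), de1 = TRUE)[["c4"]])
})

test_that("zero-count ratios follow the documented conventions", {
  # x/0 counts as infinite
  f <- evaluatePair(c(20, 0), c(0, 20), de1 = TRUE)
  expect_true(f[["c3"]])
  # 0/0 fails
  f2 <- evaluatePair(c(20, 0), c(0, 0), de1 = TRUE)
  expect_false(f2[["c3"]])
  expect_error(evaluatePair(c(-1, 5), c(5, 5)), "non-negative")
})

test_that("criterion 5 is skipped when DE-PAC evidence is not required", {
  p <- switchParams(requireDePac = FALSE)
  f <- evaluatePair(c(20, 5), c(5, 20), total1 = 25, total2 = 25, params = p)
  expect_true(f[["c5"]]); expect_true(f[["verdict"]])
  fReq <- evaluatePair(c(20, 5), c(5, 20), total1 = 25, total2 = 25)
  expect_false(fReq[["c5"]]); expect_false(fReq[["verdict"]])
})

test_that("the verdict is symmetric in the pair and in the sample order", {
  set.seed(8)
  for (i in 1:200) {
    x <- sample(0:30, 4, replace = TRUE)
    de <- sample(c(TRUE, FALSE), 2, replace = TRUE)
    a <- evaluatePair(x[1:2], x[3:4], de1 = de[1], de2 = de[2])
    b <- evaluatePair(x[3:4], x[1:2], de1 = de[2], de2 = de[1])
    expect_identical(a[["verdict"]], b[["verdict"]])
    c_ <- evaluatePair(rev(x[1:2]), rev(x[3:4]), de1 = de[1], de2 = de[2])
    expect_identical(a[["verdict"]], c_[["verdict"]])
  }
})

test_that("scaling counts up never un-satisfies c1, c2 or c4", {
  set.seed(9)
  for (i in 1:200) {
    x <- sample(0:30, 4, replace = TRUE)
    k <- sample(2:5, 1)
    a <- evaluatePair(x[1:2], x[3:4])
    b <- evaluatePair(k * x[1:2], k * x[3:4],
                      total1 = k * sum(x[1:2]), total2 = k * sum(x[3:4]))
    for (cr in c("c1", "c2", "c4"))
      expect_false(a[[cr]] && !b[[cr]])
  }
})

test_that("verdicts equal the literal five-criterion oracle on a coarse grid", {
  vals <- c(0, 4, 5, 6, 20)
  grid <- expand.grid(p1a = vals, p1b = vals, p2a = vals, p2b = vals)
  for (i in seq_len(nrow(grid))) {
    g <- as.numeric(grid[i, ])
    got <- evaluatePair(g[1:2], g[3:4], de1 = TRUE, de2 = FALSE)
    want <- oracleSwitch(g[1], g[2], g[3], g[4],
                         tot1 = g[1] + g[2], tot2 = g[3] + g[4],
                         de1 = TRUE, de2 = FALSE)
    expect_identical(unname(got), unname(want))
  }
})

test_that("candidateGenes keeps genes with at least two PACs", {
  gr <- c(makeGeneGr("g1", "chr1", "+", 1, 1000,
                     utr5 = c(1, 100), cds = c(101, 900), utr3 = c(901, 1000)),
          makeGeneGr("g2", "chr1", "+", 2001, 3000,
                     utr5 = c(2001, 2100), cds = c(2101, 2900), utr3 = c(2901, 3000)))
  m <- loadAnnotation(gr)
  counts <- matrix(c(10L, 10L, 10L, 10L), 4, 1, dimnames = list(NULL, "A"))
  pacs <- assignRegions(clusterPAS(makePAS(c(910, 990, 950 + 2000, 2905), counts)), m)
  expect_identical(candidateGenes(pacs), c("g1", "g2"))
  one <- assignRegions(clusterPAS(makePAS(910, counts[1, , drop = FALSE])), m)
  expect_length(candidateGenes(one), 0L)
})

test_that("detectSwitching evaluates all pairs and reports direction", {
  gr <- makeGeneGr("g1", "chr1", "+", 1, 1000,
                   utr5 = c(1, 100), cds = c(101, 900), utr3 = c(901, 1000))
  m <- loadAnnotation(gr)
  # proximal PAC at 920 dominant in A, distal at 990 dominant in B
  counts <- matrix(c(40L, 8L,    # proximal: A1 B1
                     8L, 40L),   # distal:   A1 B1
                   nrow = 2, byrow = TRUE, dimnames = list(NULL, c("A1", "B1")))
  pacs <- assignRegions(clusterPAS(makePAS(c(920, 990), counts)), m)
  de <- S4Vectors::DataFrame(significant = c(TRUE, TRUE),
                             row.names = rowData(pacs)$pac_id)
  ev <- detectSwitching(pacs, "A1", "B1", dePac = de)
  expect_identical(nrow(ev), 1L)
  expect_true(ev$verdict)
  expect_identical(ev$direction, "proximal_to_distal")
  expect_identical(switchingGenes(ev), "g1")

  # a gene with three PACs yields three pairs
  counts3 <- matrix(c(40L, 8L, 8L, 40L, 20L, 20L), nrow = 3, byrow = TRUE,
                    dimnames = list(NULL, c("A1", "B1")))
  pacs3 <- assignRegions(clusterPAS(makePAS(c(920, 960, 1000), counts3)), m)
  de3 <- S4Vectors::DataFrame(significant = rep(TRUE, 3),
                              row.names = rowData(pacs3)$pac_id)
  ev3 <- detectSwitching(pacs3, "A1", "B1", dePac = de3)
  expect_identical(nrow(ev3), 3L)

  # empty candidate set
  empty <- assignRegions(clusterPAS(makePAS(920, counts[1, , drop = FALSE])), m)
  expect_identical(nrow(detectSwitching(empty, "A1", "B1", dePac = de)), 0L)
  # unknown groups are a usage error
  expect_error(detectSwitching(pacs, "A1", "ZZ", dePac = de), "group")
})

test_that("relaxing the DE-PAC requirement is monotone in recall", {
  cfg <- simConfig(nGenes = 60, nSwitchGenes = 6, expressionMean = 100, seed = 37)
  sim <- generateGenome(cfg)
  tg <- simulateTags(sim, cfg)
  pacs <- assignRegions(filterPACs(clusterPAS(buildPAS(tg$tags))),
                        loadAnnotation(sim$features))
  gA <- paste0("A_rep", 1:3); gB <- paste0("B_rep", 1:3)
  dp <- deTest(pacs, gA, gB, alpha = 0.05)
  evStrict <- detectSwitching(pacs, gA, gB, dePac = dp)
  evLoose <- detectSwitching(pacs, gA, gB, switchParams(requireDePac = FALSE))
  truthSw <- sim$truth$genes$gene_id[sim$truth$genes$switch]
  recStrict <- mean(truthSw %in% switchingGenes(evStrict))
  recLoose <- mean(truthSw %in% switchingGenes(evLoose))
  expect_gte(recLoose, recStrict)
  expect_gte(recStrict, 0.5)
})

test_that("per-replicate evaluation is stricter than group-sum evaluation", {
  gr <- makeGeneGr("g1", "chr1", "+", 1, 1000,
                   utr5 = c(1, 100), cds = c(101, 900), utr3 = c(901, 1000))
  m <- loadAnnotation(gr)
  # group sums pass every criterion, but replicate A2 has no proximal reads
  counts <- matrix(c(40L, 0L, 10L, 10L,
                     5L, 5L, 40L, 40L),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(NULL, c("A1", "A2", "B1", "B2")))
  pacs <- assignRegions(clusterPAS(makePAS(c(920, 990), counts)), m)
  de <- S4Vectors::DataFrame(significant = c(TRUE, TRUE),
                             row.names = rowData(pacs)$pac_id)
  evSum <- detectSwitching(pacs, c("A1", "A2"), c("B1", "B2"), dePac = de)
  evRep <- detectSwitching(pacs, c("A1", "A2"), c("B1", "B2"), dePac = de,
                           perReplicate = TRUE)
  expect_true(evSum$verdict)
  expect_false(evRep$verdict)
})
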