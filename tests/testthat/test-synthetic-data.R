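# The synthetic-data generator: determinism, planted architecture, tag
# statistics, and FASTQ/BED emission.

test_that("simConfig validates its invariants", {
  expect_s4_class(simConfig(), "SimConfig")
  expect_error(simConfig(siteRegionMix = c(utr3 = 0.5, cds = 0.5, downstream = 0.5)),
               "sum to 1")
  expect_error(simConfig(cleavageJitterSD = -1), "JitterSD")
  expect_error(simConfig(nSwitchGenes = 10, nGenes = 5), "exceeds")
  expect_error(simConfig(genomeLength = 100), NA)  # sizing checked at generation
  expect_error(generateGenome(simConfig(nGenes = 10, genomeLength = 100)),
               "too small")
})

test_that("generateGenome is byte-deterministic under a fixed seed", {
  cfg <- simConfig(nGenes = 15, seed = 42)
  s1 <- generateGenome(cfg)
  s2 <- generateGenome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$features, s2$features)
  expect_identical(s1$truth$sites, s2$truth$sites)
})

test_that("the annotation contains exactly nGenes gene records, both strands", {
  sim <- generateGenome(simConfig(nGenes = 10, seed = 1))
  genesGr <- sim$features[sim$features$type == "gene"]
  expect_equal(length(genesGr), 10L)
  expect_true(all(c("+", "-") %in% as.character(strand(genesGr))))
  # every gene has CDS and both UTRs
  expect_equal(sum(sim$features$type == "CDS"), 10L)
  expect_equal(sum(sim$features$type == "three_prime_UTR"), 10L)
})

test_that("decoy tracts appear in the configured fraction of genes", {
  cfg <- simConfig(nGenes = 200, decoyFraction = 0.5, seed = 7)
  sim <- generateGenome(cfg)
  g <- sim$truth$genes
  # count >=8-A tracts on the transcript strand in the emitted FASTA
  hasTract <- vapply(seq_len(nrow(g)), function(i) {
    s <- subseq(sim$genome[[1]], g$start[i], g$end[i])
    if (g$strand[i] == "-") s <- reverseComplement(s)
    grepl("AAAAAAAA", as.character(s), fixed = TRUE)
  }, logical(1))
  expect_identical(hasTract, g$has_decoy)
  # ~100 of 200 within binomial tolerance (4 sd)
  expect_gt(sum(hasTract), 100 - 4 * sqrt(200 * 0.25))
  expect_lt(sum(hasTract), 100 + 4 * sqrt(200 * 0.25))
})

test_that("an A-rich AATAAA element sits ~25 nt upstream of every site", {
  sim <- generateGenome(simConfig(nGenes = 40, seed = 3))
  st <- sim$truth$sites
  g <- sim$truth$genes[match(st$gene_id, sim$truth$genes$gene_id), ]
  up <- vapply(seq_len(nrow(st)), function(i) {
    if (st$strand[i] == "+") {
      as.character(subseq(sim$genome[[1]], st$position[i] - 30, st$position[i] - 25))
    } else {
      as.character(reverseComplement(
        subseq(sim$genome[[1]], st$position[i] + 25, st$position[i] + 30)))
    }
  }, "")
  expect_true(all(up == "AATAAA"))
})

test_that("simulateTags honours usage, jitter and artifact settings", {
  cfg <- simConfig(nGenes = 50, nSwitchGenes = 5, expressionMean = 50,
                   cleavageJitterSD = 0, internalPrimingRate = 0, seed = 11)
  sim <- generateGenome(cfg)
  tg <- simulateTags(sim, cfg)
  expect_false(any(tg$tags$artifact))
  # jitter 0: every tag position is a planted site position
  expect_true(all(start(tg$tags) %in% sim$truth$sites$position))
  # per-tag truth is complete
  expect_true(all(tg$tags$site_id %in% c(sim$truth$sites$site_id, "ip_artifact")))

  cfgIp <- simConfig(nGenes = 50, expressionMean = 50, cleavageJitterSD = 0,
                     internalPrimingRate = 0.25, seed = 11)
  tgIp <- simulateTags(generateGenome(cfgIp), cfgIp)
  fr <- mean(tgIp$tags$artifact)
  expect_gt(fr, 0.2); expect_lt(fr, 0.3)
})

test_that("per-gene per-replicate counts match the NB mean", {
  cfg <- simConfig(nGenes = 200, expressionMean = 200, seed = 5)
  tg <- simulateTags(generateGenome(cfg), cfg)
  perGeneRep <- length(tg$tags) / (200 * 6)
  expect_gt(perGeneRep, 180); expect_lt(perGeneRep, 220)
})

test_that("emitFastq writes reads with the oligo-dT structure and exact 3' ends", {
  cfg <- simConfig(nGenes = 30, expressionMean = 60, cleavageJitterSD = 0,
                   noPolyTFraction = 0.1, seed = 9)
  sim <- generateGenome(cfg)
  tg <- simulateTags(sim, cfg)
  d <- withr::local_tempdir()
  man <- emitFastq(tg, sim$genome, cfg, d)
  expect_identical(sum(man$n_reads), length(tg$tags))   # conservation

  reads <- Biostrings::readDNAStringSet(man$file[1], format = "fastq")
  n <- length(reads)
  noT <- sum(!grepl("^TTTTTTTT", as.character(reads)))
  expect_lt(abs(noT - 0.1 * n), 4 * sqrt(n * 0.1 * 0.9) + 1)

  # a read's sequence after poly(T) removal, reverse-complemented, matches
  # the genome ending at its truth cleavage position
  tags <- tg$tags
  for (nm in head(names(reads)[grepl("^TTTTTTTT", as.character(reads))], 25)) {
    s <- as.character(reads[[nm]])
    body <- sub("^T+", "", s)
    u <- as.character(reverseComplement(DNAString(body)))
    tr <- tags[nm]
    p <- start(tr)
    gseq <- if (as.character(strand(tr)) == "+") {
      as.character(subseq(sim$genome[[1]], p - nchar(u) + 1, p))
    } else {
      as.character(reverseComplement(
        subseq(sim$genome[[1]], p, p + nchar(u) - 1)))
    }
    # trimming may eat genuine 3' A-bases; require suffix match
    expect_true(endsWith(gseq, u) || endsWith(u, gseq))
  }

  # byte determinism
  d2 <- withr::local_tempdir()
  man2 <- emitFastq(tg, sim$genome, cfg, d2)
  expect_identical(readLines(man$file[1]), readLines(man2$file[1]))
})

test_that("emitBed/readTagBed round-trip the tag multiset and conventions", {
  cfg <- simConfig(nGenes = 20, expressionMean = 20, seed = 13)
  sim <- generateGenome(cfg)
  tg <- simulateTags(sim, cfg)
  d <- withr::local_tempdir()
  man <- emitBed(tg, d)
  expect_identical(sum(man$n_tags), length(tg$tags))
  back <- do.call(c, lapply(seq_len(nrow(man)), function(i)
    readTagBed(man$file[i], man$sample[i])))
  orig <- tg$tags[order(tg$tags$sample_id)]
  expect_identical(start(back), start(orig))
  expect_identical(as.character(strand(back)), as.character(strand(orig)))

  # BED text convention: 0-based half-open single base at the cleavage site
  l1 <- strsplit(readLines(man$file[1], n = 1), "\t")[[1]]
  first <- tg$tags[tg$tags$sample_id == man$sample[1]][1]
  expect_identical(as.integer(l1[2]), start(first) - 1L)
  expect_identical(as.integer(l1[3]), start(first))
  expect_identical(l1[6], as.character(strand(first)))
})

test_that("jitter-free, artifact-free data reproduce planted sites through the PAC stage", {
  cfg <- simConfig(nGenes = 40, expressionMean = 80, cleavageJitterSD = 0,
                   internalPrimingRate = 0, seed = 21)
  sim <- generateGenome(cfg)
  tg <- simulateTags(sim, cfg)
  pacs <- filterPACs(clusterPAS(buildPAS(tg$tags)))
  expect_true(all(representativePositions(pacs) %in% sim$truth$sites$position))
})
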