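# Pipeline orchestration: a single structured configuration drives
# simulate -> preprocess -> map -> PAC building -> annotation -> DE ->
# switching -> composition profiles, with per-stage counts and a run
# manifest.

#' Build a pipeline run configuration
#'
#' The configuration is a plain nested list (YAML-serialisable with
#' [writeRunConfig()]/[readRunConfig()]). In `"simulate"` mode the
#' synthetic generator produces genome, annotation and per-sample FASTQ
#' (or BED) inputs inside the output directory; in `"fastq"`/`"bed"` mode
#' the genome, annotation and a sample sheet (TSV: sample, group, file)
#' must be supplied.
#'
#' @param outDir output directory for all stage results.
#' @param mode `"simulate"`, `"fastq"` or `"bed"`.
#' @param sim named list of [simConfig()] overrides (simulate mode).
#' @param simInput in simulate mode, feed the pipeline from emitted
#'   `"fastq"` reads (full preprocessing) or pre-mapped `"bed"` tags.
#' @param genome,annotation,sampleSheet paths (fastq/bed mode).
#' @param preprocess,pac,switching named lists of [preprocessParams()],
#'   [pacParams()] and [switchParams()] overrides.
#' @param geneAlpha,pacAlpha adjusted-p thresholds for DE genes (default
#'   0.01) and DE PACs (default 0.05).
#' @param extension 3'UTR extension in nt (default 120).
#' @param comparisons list of 2-vectors of group labels to compare;
#'   defaults to the first two simulated conditions.
#' @param profileRegions region labels to profile (default `"3UTR"`).
#' @param seed integer seed governing every stochastic step.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(outDir, mode = c("simulate", "fastq", "bed"),
                      sim = list(), simInput = c("fastq", "bed"),
                      genome = NULL, annotation = NULL, sampleSheet = NULL,
                      preprocess = list(), pac = list(), switching = list(),
                      geneAlpha = 0.01, pacAlpha = 0.05, extension = 120L,
                      comparisons = NULL, profileRegions = "3UTR",
                      seed = 1L) {
  cfg <- list(outDir = outDir, mode = match.arg(mode),
              sim = sim, simInput = match.arg(simInput),
              genome = genome, annotation = annotation,
              sampleSheet = sampleSheet,
              preprocess = preprocess, pac = pac, switching = switching,
              geneAlpha = geneAlpha, pacAlpha = pacAlpha,
              extension = as.integer(extension),
              comparisons = comparisons, profileRegions = profileRegions,
              seed = as.integer(seed))
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' @rdname runConfig
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(runConfig, cfg[!vapply(cfg, is.null, TRUE)])
}

.tryParams <- function(fun, overrides, label) {
  tryCatch({
    do.call(fun, overrides)
    character(0)
  }, error = function(e) paste0(label, ": ", conditionMessage(e)))
}

#' Validate a run configuration
#'
#' Report-only check of every configuration invariant: parameter bundles
#' must validate, referenced paths must exist, comparisons must reference
#' known groups, and sample ids must be unique.
#'
#' @param config a `RunConfig` list from [runConfig()].
#' @return character vector of violations; empty when the configuration
#'   is valid.
#' @export
validateRunConfig <- function(config) {
  v <- character(0)
  if (!config$mode %in% c("simulate", "fastq", "bed"))
    v <- c(v, "mode: must be simulate, fastq or bed")
  v <- c(v, .tryParams(preprocessParams, config$preprocess, "preprocess"))
  v <- c(v, .tryParams(pacParams, config$pac, "pac"))
  v <- c(v, .tryParams(switchParams, config$switching, "switching"))
  for (a in c("geneAlpha", "pacAlpha"))
    if (!is.numeric(config[[a]]) || config[[a]] <= 0 || config[[a]] > 1)
      v <- c(v, paste0(a, ": must be in (0, 1]"))

  groups <- NULL
  if (config$mode == "simulate") {
    simErr <- .tryParams(simConfig, config$sim, "sim")
    v <- c(v, simErr)
    if (!length(simErr))
      groups <- do.call(simConfig, config$sim)@conditions
  } else {
    for (p in c("genome", "annotation", "sampleSheet")) {
      if (is.null(config[[p]]))
        v <- c(v, paste0(p, ": required in ", config$mode, " mode"))
      else if (!file.exists(config[[p]]))
        v <- c(v, paste0(p, ": file not found: ", config[[p]]))
    }
    if (!is.null(config$sampleSheet) && file.exists(config$sampleSheet)) {
      sh <- read.table(config$sampleSheet, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
      if (!all(c("sample", "group", "file") %in% colnames(sh)))
        v <- c(v, "sampleSheet: needs columns sample, group, file")
      else {
        if (anyDuplicated(sh$sample))
          v <- c(v, "sampleSheet: duplicate sample ids")
        groups <- unique(sh$group)
      }
    }
  }
  if (!is.null(config$comparisons) && !is.null(groups)) {
    for (cmp in config$comparisons) {
      missing <- setdiff(cmp, groups)
      if (length(missing))
        v <- c(v, paste0("comparisons: unknown group(s) ",
                         paste(missing, collapse = ", ")))
    }
  }
  v
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

.pacTable <- function(pacs) {
  rr <- rowRanges(pacs)
  rd <- rowData(pacs)
  base <- data.frame(chrom = as.character(seqnames(rr)),
                     start = start(rr), end = end(rr),
                     strand = as.character(strand(rr)),
                     pac_id = rd$pac_id,
                     representative = rd$representative,
                     n_sites = rd$n_sites,
                     stringsAsFactors = FALSE)
  if ("gene_id" %in% colnames(rd)) {
    base$gene_id <- rd$gene_id
    base$region <- rd$region
  }
  cbind(base, as.data.frame(assay(pacs, "counts")))
}

#' Run the full pipeline
#'
#' Executes all stages in order (simulate where configured, then
#' preprocess, map, PAS/PAC building, annotation, gene- and PAC-level
#' differential expression for every comparison, switching detection and
#' composition profiles), writes every result as TSV under
#' `config$outDir`, and records parameters and per-stage counts in
#' `manifest.json`. Re-running with an identical configuration reproduces
#' identical outputs. On failure the output directory is marked with a
#' `STALE` file naming the failed stage.
#'
#' @param config a `RunConfig` list from [runConfig()].
#' @return Invisibly, a list with the main in-memory results: `pacs`
#'   (annotated [PACSet-class]), `geneCounts`, `deGene`, `dePac`,
#'   `switch` (per comparison), `profiles`, `stageCounts` and `manifest`.
#' @export
runPipeline <- function(config) {
  violations <- validateRunConfig(config)
  if (length(violations))
    stopf("invalid configuration:\n  %s", paste(violations, collapse = "\n  "))
  out <- config$outDir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  stale <- file.path(out, "STALE")
  if (file.exists(stale)) unlink(stale)
  counts <- list()

  res <- tryCatch({
    ppPar <- do.call(preprocessParams, config$preprocess)
    pacPar <- do.call(pacParams, config$pac)
    swPar <- do.call(switchParams, config$switching)

    if (config$mode == "simulate") {
      scfg <- do.call(simConfig, c(config$sim, list(seed = config$seed)))
      sim <- .stage("simulate", generateGenome(scfg))
      tagSim <- .stage("simulate", simulateTags(sim, scfg))
      simDir <- file.path(out, "sim")
      if (!dir.exists(simDir)) dir.create(simDir)
      writeXStringSet(sim$genome, file.path(simDir, "genome.fa"))
      rtracklayer::export(sim$features, file.path(simDir, "annotation.gff3"),
                          format = "gff3")
      writeTsv(tagSim$samples, file.path(simDir, "sample_sheet.tsv"))
      writeTsv(sim$truth$sites, file.path(simDir, "truth_sites.tsv"))
      writeTsv(sim$truth$genes, file.path(simDir, "truth_genes.tsv"))
      genome <- sim$genome
      annotation <- sim$features
      sheet <- data.frame(sample = tagSim$samples$sample,
                          group = tagSim$samples$condition,
                          stringsAsFactors = FALSE)
      if (config$simInput == "fastq") {
        fq <- emitFastq(tagSim, genome, scfg, simDir)
        sheet$file <- fq$file
      } else {
        bed <- emitBed(tagSim, simDir)
        sheet$file <- bed$file
      }
      counts$simulate <- c(n_genes = scfg@nGenes, n_tags = length(tagSim$tags))
      readMode <- config$simInput
    } else {
      genome <- readDNAStringSet(config$genome)
      names(genome) <- sub("\\s.*$", "", names(genome))
      annotation <- config$annotation
      sheet <- read.table(config$sampleSheet, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
      readMode <- if (config$mode == "fastq") "fastq" else "bed"
    }

    sampleNames <- sheet$sample
    tagList <- vector("list", nrow(sheet))
    for (i in seq_len(nrow(sheet))) {
      if (readMode == "fastq") {
        qf <- .stage("preprocess", qualityFilter(sheet$file[i], ppPar))
        tr <- .stage("preprocess", trimTags(qf$reads, ppPar))
        mp <- .stage("map", mapTags(tr$tags, genome, sheet$sample[i]))
        counts[[paste0("preprocess_", sheet$sample[i])]] <-
          c(qf$counts, tr$counts[-1], mp$counts[-1])
        tagList[[i]] <- mp$tags
      } else {
        tagList[[i]] <- .stage("import", readTagBed(sheet$file[i], sheet$sample[i]))
        counts[[paste0("import_", sheet$sample[i])]] <-
          c(n_tags = length(tagList[[i]]))
      }
    }
    tags <- do.call(c, tagList)
    tags$sample_id <- factor(as.character(tags$sample_id), levels = sampleNames)

    pas <- .stage("build-pacs", buildPAS(tags, samples = sampleNames))
    ip <- .stage("build-pacs", filterInternalPriming(pas, genome, pacPar))
    pacsAll <- .stage("build-pacs", clusterPAS(ip$retained, pacPar))
    pacs <- .stage("build-pacs", filterPACs(pacsAll, pacPar))
    counts$build_pacs <- c(n_pas = nrow(pas),
                           n_pas_ip_removed = nrow(ip$removed),
                           n_pacs = nrow(pacsAll),
                           n_pacs_supported = nrow(pacs))

    models <- .stage("annotate", loadAnnotation(annotation, config$extension))
    pacs <- .stage("annotate", assignRegions(pacs, models))
    gc <- .stage("annotate", geneCounts(pacs))
    counts$annotate <- c(n_genes_with_pacs = nrow(gc$genes),
                         n_intergenic_pacs = nrow(gc$intergenic))
    writeTsv(.pacTable(pacs), file.path(out, "pac_table.tsv"))
    writeTsv(cbind(gene_id = rownames(assay(gc$genes, "counts")),
                   as.data.frame(assay(gc$genes, "counts"))),
             file.path(out, "gene_counts.tsv"))
    if (nrow(gc$intergenic))
      writeTsv(.pacTable(gc$intergenic), file.path(out, "intergenic_pacs.tsv"))

    comparisons <- config$comparisons
    if (is.null(comparisons))
      comparisons <- list(unique(sheet$group)[1:2])
    deGene <- list(); dePac <- list(); sw <- list()
    for (cmp in comparisons) {
      tag <- paste0(cmp[1], "_vs_", cmp[2])
      sA <- sheet$sample[sheet$group == cmp[1]]
      sB <- sheet$sample[sheet$group == cmp[2]]
      dg <- .stage("de-gene", deTest(gc$genes, sA, sB, alpha = config$geneAlpha))
      dp <- .stage("de-pac", deTest(pacs, sA, sB, alpha = config$pacAlpha))
      ev <- .stage("switch", detectSwitching(pacs, sA, sB, swPar, dePac = dp))
      deGene[[tag]] <- dg; dePac[[tag]] <- dp; sw[[tag]] <- ev
      writeTsv(as.data.frame(dg), file.path(out, paste0("de_gene_", tag, ".tsv")))
      writeTsv(as.data.frame(dp), file.path(out, paste0("de_pac_", tag, ".tsv")))
      writeTsv(as.data.frame(ev), file.path(out, paste0("switch_", tag, ".tsv")))
      counts[[paste0("de_", tag)]] <- c(
        n_de_genes = sum(dg$significant), n_de_pacs = sum(dp$significant),
        n_switch_genes = length(switchingGenes(ev)))
    }

    profiles <- list()
    for (rg in config$profileRegions) {
      if (!any(pacRegions(pacs) == rg)) next
      w <- .stage("profile", extractWindows(pacs, genome, region = rg))
      profiles[[rg]] <- .stage("profile", baseComposition(w, region = rg))
      writeTsv(profiles[[rg]], file.path(out, paste0("profile_", rg, ".tsv")))
    }

    stageDf <- do.call(rbind, lapply(names(counts), function(nm)
      data.frame(stage = nm, metric = names(counts[[nm]]),
                 value = as.numeric(counts[[nm]]))))
    writeTsv(stageDf, file.path(out, "stage_counts.tsv"))
    manifest <- list(package = "patseqr",
                     version = as.character(packageVersion("patseqr")),
                     seed = config$seed,
                     parameters = unclass(config),
                     stage_counts = counts)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(pacs = pacs, geneCounts = gc, deGene = deGene, dePac = dePac,
         switch = sw, profiles = profiles, stageCounts = counts,
         manifest = manifest)
  }, error = function(e) {
    writeLines(conditionMessage(e), stale)
    stop(e)
  })
  invisible(res)
}
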