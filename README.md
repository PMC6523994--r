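# patseqr

Analysis of poly(A)-tag (PAT) 3'-end sequencing data in R/Bioconductor
style: from oligo-dT-primed reads to poly(A)-site clusters (PACs),
differential expression, poly(A)-site **switching** calls, and
nucleotide-composition profiles around cleavage sites.

## The problem

Most eukaryotic genes carry several cleavage/polyadenylation sites, so the
same gene can produce transcript isoforms with different 3' ends
(alternative polyadenylation, APA). PAT-Seq reads are primed from the
poly(A) tail, so each read's genomic 3' end marks one polyadenylation
event. Turning millions of such tags into biology requires a chain of
small, rule-based decisions, each of which this package implements
explicitly and tests against independent oracles:

* tags at one coordinate form a **PAS** (poly(A) site);
* a PAS whose downstream 10-nt genomic window holds ≥ 7 A or a run of
  ≥ 6 A is an **internal-priming artifact** (oligo-dT mispriming on
  genomic A-tracts) and is removed;
* PAS within **24 nt** (single-linkage, inclusive) cluster into a **PAC**;
  PACs under **10 reads** total are discarded; the most abundant member
  site represents the cluster;
* PACs are annotated against a gene model whose 3'UTRs are extended
  **120 nt** downstream (truncated at the next same-strand gene);
* genes and PACs are tested for differential expression with
  median-of-ratios normalisation and a negative-binomial Wald test
  (genes padj < 0.01, PACs padj < 0.05);
* a gene **switches** poly(A) sites between two sample groups when some
  PAC pair (PA1, PA2) satisfies all of: (1) PA1 or PA2 ≥ 5 reads in each
  group; (2) PA1 or PA2 ≥ 20 reads over all samples; (3) PA1/PA2 ≥ 2 in
  one group and PA2/PA1 ≥ 2 in the other; (4) |PA1 − PA2| > 5 in both
  groups; (5) one of the pair is a significant DE-PAC.

A synthetic-data generator (`simConfig()`, `generateGenome()`,
`simulateTags()`, `emitFastq()`/`emitBed()`) produces toy genomes, GFF3
annotations and reads with complete ground truth — planted switching
genes, internal-priming decoys, AATAAA-class upstream elements — and is
the basis of the package's validation. See the vignette in `vignettes/`
for the models, conventions and their rationale.

## Worked example

Simulate the package's standard study (200 genes, 10 switching genes with
a 0.8/0.2 usage flip, NB mean 200, two conditions × three replicates),
run the PAC pipeline and call switching genes:

```r
library(patseqr)

cfg <- simConfig(seed = 1)
sim <- generateGenome(cfg)
tg  <- simulateTags(sim, cfg)

pas  <- buildPAS(tg$tags)
ip   <- filterInternalPriming(pas, sim$genome)
pacs <- filterPACs(clusterPAS(ip$retained))
pacs <- assignRegions(pacs, loadAnnotation(sim$features))
pacs
#> PACSet with 395 poly(A)-site clusters, 6 samples, 240573 tags
#>   regions: 3UTR=312, CDS=38, intergenic=45

gA <- paste0("A_rep", 1:3); gB <- paste0("B_rep", 1:3)
dePac  <- deTest(pacs, gA, gB, alpha = 0.05)
events <- detectSwitching(pacs, gA, gB, dePac = dePac)
switchingGenes(events)
#>  [1] "gene0010" "gene0022" "gene0048" "gene0075" "gene0086" "gene0117"
#>  [7] "gene0132" "gene0182" "gene0184" "gene0199"

truth <- sim$truth$genes$gene_id[sim$truth$genes$switch]
identical(sort(truth), switchingGenes(events))
#> [1] TRUE
```

All ten planted switching genes are recovered with no false positives.
The 395 PACs split roughly 80/10/10 across 3'UTR, CDS and intergenic
regions — the generator's planted mix. `runPipeline(runConfig(...))`
wraps the same stages (including FASTQ emission, quality filtering,
oligo-dT trimming and mapping) behind a single YAML-serialisable
configuration and writes every result as TSV plus a `manifest.json` of
parameters and per-stage counts; reruns with the same seed are
byte-identical.

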