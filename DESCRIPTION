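Package: patseqr
Title: Poly(A)-Tag Sequencing Analysis: Cleavage-Site Clustering and
    Alternative-Polyadenylation Switching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for poly(A)-tag (PAT) 3'-end sequencing
    data: read-level quality filtering and oligo-dT trimming, tag mapping,
    aggregation of tags into poly(A) sites (PAS), removal of internal-priming
    artifacts at A-rich genomic tracts, single-linkage clustering of PAS into
    poly(A)-site clusters (PACs), annotation of PACs against a gene model with
    extended 3'UTRs, median-of-ratios normalisation with negative-binomial
    differential expression at the gene and PAC level, rule-based detection of
    poly(A)-site switching genes between sample groups, and strand-aware
    nucleotide-composition profiles around cleavage sites. Ships a synthetic
    data generator that emits toy genomes, GFF3 annotations and PAT reads with
    known ground truth for validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
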