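---
title: "Methods: poly(A)-tag processing, PAC calling and switching detection"
author: "patseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poly(A)-tag processing, PAC calling and switching detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patseqr)
```

# Overview

`patseqr` analyses poly(A)-tag (PAT) 3'-end sequencing data. A PAT read is
primed from the poly(A) tail with an anchored oligo-dT primer, so after
removal of the poly(T) read-through its 3' end marks one cleavage and
polyadenylation event on the genome. The pipeline moves from reads to
biology in fixed stages:

1. **Preprocess** — quality filtering, oligo-dT trimming, length filter.
2. **Map** — exact placement of trimmed tags on a toy-scale genome (real
   data enters as pre-mapped BED).
3. **PAC building** — tags with the same cleavage coordinate form a
   poly(A) site (PAS); A-rich internal-priming artifacts are removed; PAS
   within 24 nt chain into poly(A)-site clusters (PACs); weakly supported
   PACs are discarded; the most abundant member site represents each PAC.
4. **Annotation** — PACs are assigned to genes and regions against a GFF3
   model whose 3'UTRs are extended 120 nt downstream.
5. **Statistics** — median-of-ratios normalisation, negative-binomial
   differential expression of genes (padj < 0.01) and PACs (padj < 0.05),
   and a five-criterion rule for poly(A)-site switching between sample
   groups.
6. **Profiles** — strand-aware single-nucleotide composition in the
   −300..+100 window around representative cleavage sites.

A synthetic-data generator emits toy genomes, annotations and reads with
full ground truth; it is first-class, tested code and drives the
package's validation.

# Conventions

**Coordinates.** All internal containers are Bioconductor objects
(`GRanges`, `RangedSummarizedExperiment`), hence 1-based inclusive
coordinates. BED input/output is 0-based half-open and converted by
`rtracklayer`. The **cleavage position** of a tag is the last transcribed
genomic base: the 3'-most aligned base on the plus strand, the 5'-most
genomic coordinate on the minus strand. Every PAS, every PAC
representative and every profile window is anchored on that base (index 0
in profiles).

**Read structure.** Simulated reads are emitted as sequenced from the
oligo-dT end: a poly(T) prefix (8–20 nt, the reverse-complemented start
of the tail) followed by the reverse complement of the transcript-strand
sequence upstream of the cleavage site. The pipeline must therefore trim
the prefix and reverse-complement to map — the same operations real PAT
data requires.

# Preprocessing

Quality filtering keeps a read iff at least `minPercentAtQuality`% of its
bases reach Phred `minQuality` (defaults 50% and Q10, boundary
inclusive). Oligo-dT trimming removes the longest leading poly(T) run; one
mismatch is tolerated after ten consecutive T to absorb the primer's
anchored base. A read with a leading run shorter than `minPolyTRun`
(default 8 nt) carries no oligo-dT evidence and is discarded, as are
trimmed tags shorter than 20 nt. The thresholds for the oligo-dT evidence
are configurable because the chemistry leaves them under-determined: any
genomic A-run adjacent to the cleavage site is indistinguishable from
tail-derived T bases in the read, so trimmed 3' ends can shift upstream by
the length of that run. The generator plants non-A bases at and directly
before each true site, which makes recovery exact on jitter-free
synthetic data; on real data this ambiguity is irreducible and cleavage
positions should be read as "within the local A context".

The built-in mapper does exact substring search of each tag's reverse
complement against both genome orientations (one `PDict` per orientation
with a trusted band over the shortest tag). Multi-mapping or unmatched
tags are dropped and counted. This is intentionally a toy-scale stand-in:
users with real data import pre-mapped tag 3' ends as BED6.

# PAS, internal priming, and PACs

Tags sharing (chromosome, strand, position) form one PAS with per-sample
counts. A PAS is flagged as an **internal-priming artifact** when the
10-nt transcript-strand window immediately downstream of the cleavage
site contains ≥ 7 adenosines or a run of ≥ 6 consecutive adenosines —
the field-standard heuristic for oligo-dT mispriming on genomic A
stretches; window size and both thresholds are exposed in `pacParams()`.
Windows truncated by a chromosome end treat missing bases as non-A and
warn.

PAS are then clustered **single-linkage per chromosome and strand**:
consecutive sites whose positional gap is ≤ 24 nt (inclusive: a gap of
exactly 24 merges) join the same PAC. Single-linkage chaining, rather
than a fixed window, was chosen because it is order-independent and has a
clean transitive-closure definition that the tests verify against an
independent oracle. PACs supported by fewer than 10 reads summed over all
samples are discarded. The representative position is the member PAS with
the highest total count; ties break to the 3'-most position in
transcription direction (a deterministic, documented rule — the
convention is otherwise arbitrary).

# Annotation

`loadAnnotation()` parses a GFF3 gene model and extends every 3'UTR by
120 nt in transcription direction, because genuine cleavage sites
frequently fall downstream of annotated gene ends. The extension is
truncated at the next same-strand gene, which prevents mis-assignment in
compact genomes. Each PAC is tested at its representative position with
precedence extended-3'UTR > CDS > 5'UTR > intron; a hit in the extension
is still labelled `3UTR`. When overlapping genes compete, the gene whose
3' end is nearest wins. PACs hitting nothing are intergenic; they are
excluded from gene-level counting but returned separately so totals are
conserved.

# Expression statistics

Size factors are median-of-ratios: the median over features (nonzero in
every sample) of the count-to-geometric-mean ratio, rescaled to geometric
mean one. The two-group test is a negative-binomial Wald test on the log2
fold change of normalised group means, with a 0.5 pseudocount
stabilising low counts. Per-feature dispersions come from the pooled
within-group variance by method of moments. With three replicates these
raw estimates are extremely noisy and their median is biased low (the
pooled variance is roughly a scaled chi-square with few degrees of
freedom), which makes a naive Wald test anticonservative. The package
therefore shrinks each estimate 50/50 toward the **global mean**
dispersion and floors it there. On null simulations at the package's
standard conditions (2,000 features, NB mean 200, dispersion 0.1, 3 vs 3)
this yields a raw-p < 0.05 fraction near 0.045 and no spurious
padj < 0.01 calls, while a planted 8-fold change is always recovered —
the calibration the test suite asserts. Features with mean normalised
count below 1 are excluded from testing (independent filtering) and
`NA`-marked; Benjamini–Hochberg correction runs over tested features
only. Without replicates the test falls back to an exact two-sided
binomial test on the pooled proportion, documented as lower power.
Gene-level calls default to padj < 0.01 and PAC-level calls to
padj < 0.05.

`enrichmentTest()` provides generic one-sided hypergeometric gene-set
enrichment with BH correction against user-supplied sets; no ontology
database is bundled.

# Switching detection

For every gene with at least two PACs, every PAC pair (PA1, PA2) is
evaluated between two sample groups on five criteria:

1. PA1 or PA2 has a count ≥ 5 in **each** group;
2. PA1 or PA2 has a total count across all samples ≥ 20;
3. PA1/PA2 ≥ 2 in one group **and** PA2/PA1 ≥ 2 in the other;
4. |PA1 − PA2| > 5 (strictly) in both groups;
5. at least one of the pair is a significant DE-PAC for the comparison
   (can be disabled).

"Sample" in these criteria means the replicate-summed counts of each
group — conditions, not individual libraries, are compared; an optional
per-replicate mode demands criteria 1, 3 and 4 in every single replicate.
Zero denominators follow x/0 = ∞ for x > 0 while 0/0 fails criterion 3.
Criterion 4 is kept strict (a difference of exactly 5 fails) in contrast
to the ≥ of criteria 1–3, and criterion 2's "all samples" means the whole
dataset. A gene switches if any pair passes all enabled criteria; the
reported direction (proximal→distal or distal→proximal) compares the
proximal site's usage share between groups, with proximal defined as the
5'-most representative position in transcription direction.

# Composition profiles

`extractWindows()` collects the transcript-strand sequence covering
relative positions −300..+99 around each representative site (a 400-nt
window with the cleavage base at index 0; minus-strand windows are
reverse-complemented). Positions outside the chromosome are masked with
`.` and excluded from denominators rather than zero-filled.
`baseComposition()` returns per-position A/C/G/T fractions, which sum to
one wherever any window covers the position. On synthetic data this
recovers the planted AATAAA-class near-upstream element as an elevated
A fraction around −25; de-novo motif discovery is out of scope.

# The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes,
with defaults that define the package's standard study: 200 intronless
genes (100 nt 5'UTR, 300 nt CDS, 200 nt 3'UTR) alternating strand along
one chromosome with 400-nt spacers; 1–3 poly(A) sites per gene drawn from
a region mix of 80% 3'UTR, 10% CDS, 10% downstream-intergenic, planted at
slots ≥ 65 nt apart so they resolve into separate PACs; per-gene usage
proportions drawn once from a symmetric Dirichlet (concentration 5) and
shared across conditions, so non-switching genes cannot switch by
construction; 10 switching genes with two 3'UTR sites 150 nt apart and
deterministic 0.8/0.2 ↔ 0.2/0.8 usage; negative-binomial expression with
mean 200 and dispersion 0.1 per gene and replicate; two conditions × three
replicates; Gaussian cleavage jitter (sd 2 nt, rounded, clamped to the
gene locus ± 300 nt); an AATAAA element at −30..−25 of every site; and a
10-A decoy tract in the CDS of half the genes, to which a configurable
fraction of tags is re-assigned as internal-priming artifacts (cleavage
immediately 5' of the tract).

Three deliberate regularisations make truth recoverable exactly:
background runs of ≥ 6 A or T are broken (decoys are the only tracts the
internal-priming filter should fire on), the two bases at and before each
cleavage site are fixed non-A (oligo-dT trimming cannot eat genuine 3'
ends), and the 10-nt window downstream of each true site is capped below
the artifact thresholds. Real data has none of these guarantees — passing
tests demonstrate that the implementation applies its stated rules
exactly, not that the rules are unambiguous on real genomes. Likewise the
generator omits sequencing errors, PCR duplicates and barcode structure
(out of scope), so preprocessing robustness to those is untested by
design.

A fixed seed makes every artifact byte-identical: the genome, tag,
and read stages each derive their RNG stream from the configured seed.

# Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data
at the standard conditions above (about 240,000 tags for the switching
study; 2,000 × 6 count matrices for DE calibration; ~20,000 tags for the
end-to-end FASTQ runs, chosen as a comfortable desk-scale problem).
Dispersion estimates are floored at 1e-8 before shrinkage; fold changes
use a 0.5 pseudocount; profile fractions use exact integer counts.
Degenerate inputs are defined behaviour: empty tag sets produce empty
PAS/PAC sets, empty candidate sets produce empty switching tables,
all-intergenic annotations produce an empty gene matrix plus a full
intergenic report, and identical groups give log2FC 0 with p = 1.

# Known limitations

The exact mapper requires toy-scale genomes and exact matches; real
studies should import aligned tag BEDs. The DE module implements a single
two-group comparison (no multi-factor designs, no LFC shrinkage a la
apeglm, no outlier handling). Switching is a binary rule set, not a
continuous usage statistic with its own sampling model. Intergenic PACs
never enter gene counts; whether that is appropriate depends on the
annotation's completeness — the 120-nt extension is the only mechanism
reclaiming downstream sites.
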