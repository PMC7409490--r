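---
title: "methylGEM: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methylGEM: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylGEM)
```

# What the package computes

methylGEM implements an integrative epigenetic analysis for tumor cohorts
profiled by reduced-representation bisulfite sequencing (RRBS-style per-CpG
methylated/unmethylated read counts), expression arrays or RNA-seq (a
normalized log2 matrix), and chromatin interval data (histone-mark,
super-enhancer and CTCF BED files). The motivating setting is newly
diagnosed multiple myeloma, where molecular subgroups defined by IgH
translocations or hyperdiploidy carry distinct methylation landscapes and
where promoter methylation is inversely, and gene-body methylation
positively, correlated with expression. The pipeline:

1. **calls DMRs** (differentially methylated regions) per tumor subgroup
   against controls from multi-CpG regions,
2. **calls DMCs** (differentially methylated cytosines) from array
   beta-value tables,
3. **annotates** each DMR to the promoter, gene-body or intergenic
   compartment of its nearest-TSS gene and computes the relative distance
   statistic *D*,
4. **classifies GEMs** — genes whose expression correlates with DNA
   methylation — by intersecting DMR direction/compartment with two-fold
   expression changes,
5. **overlays chromatin intervals** (>50 bp overlap rule) and clusters
   SE/CTCF-DMR methylation profiles into modules, and
6. **summarizes** cohort structure (top-variable selection, hierarchical
   clustering, PCA, per-subgroup composition).

Because the motivating patient cohort is not publicly deposited, the
package ships a first-class synthetic-cohort generator with a planted
truth table; all quantitative guarantees are property-based (recovery,
calibration, oracle equivalence) rather than reproductions of cohort
numbers.

# The DMR model

## Qualification filters

A CpG enters the analysis only if it has at least `minReads = 10` reads in
*every* sample. Regions are maximal runs of retained CpGs with inter-CpG
gaps of at most `maxGap = 200` bp, split so no region spans more than
`maxSpan = 220` bp, and must contain at least `minCpgs = 2` CpGs.
Per-sample region methylation is the pooled percentage
$100 \cdot \sum m_i / \sum t_i$ over member CpGs.

The original analysis derived regions from MspI restriction fragments;
fragment boundaries require a reference genome, so this package assembles
gap-bounded CpG runs at the same granularity (MspI fragments selected in
RRBS libraries are roughly 40-220 bp). The assembly is a separate,
pluggable stage: any `MethylRegionSet` can be fed to the calling
functions.

A region then passes the **methylation-band filter** only if the mean
methylation of *both* the control and the subgroup lies in
$[20, 40] \cup [60, 80]$ percent — not above 80, not below 20, and not
strictly between 40 and 60. The outer boundaries are read as closed and
the middle band as open; all four boundaries are exposed as arguments.
The filter is applied to each group mean independently (the qualification
sentence is a conjunction over the two groups).

An important, easily overlooked consequence: **a 20-point methylation
shift cannot robustly pass the band filter**, because no 20-point-wide
sub-band contains both the control level and the shifted level away from
a boundary. The planted-recovery benchmarks therefore run
`callDMRs(band = FALSE)` and measure the detection engine (ANOVA + BH +
delta gate); the band rule itself is verified exactly against a
rule-by-rule oracle on constructed boundary cases.

## The test

Significance is a two-way ANOVA on per-sample, per-CpG methylation
percentages with additive factors *group* and *CpG position*; the group
main-effect p-value is reported. The named test leaves the design open;
this package fixes it as the additive model without interaction (there is
no replication to support an interaction at typical coverage). After the
coverage filter the design is complete and balanced in positions, so the
two factors are orthogonal and the group sum of squares has a closed form
(`anovaGroupP`), verified against `anova(lm(...))` in the tests. Regions
with zero residual variance (e.g. all samples 0% or 100%) return `NA` and
are excluded from calling.

The ANOVA treats CpG-level observations as independent replicates. If
patients carry region-level methylation offsets (they do), residuals are
correlated within a sample and the test is mildly anti-conservative.
For this reason (a) the generator's per-sample jitter default is small
(see below) and (b) the type-I calibration test simulates the null under
the test's own independence assumption (`jitter_concentration = Inf`).

## Multiple testing and gates

All regions tested for one subgroup-vs-control contrast form one
Benjamini-Hochberg family; subgroups are corrected independently. A region
is a DMR iff $|\Delta| \ge$ `minDelta` (10 percentage points) *and*
$q <$ `alpha` (0.05). The delta gate uses group means; the median DMR
methylation (MDM, the per-group median of per-sample region percentages)
is reported alongside, since the delta-versus-median choice is ambiguous
in the source analysis. Because the q-values are computed on the full
tested family before gating, applying the delta gate before or after the
FDR step yields the same call set (tested).

## DMCs

Array probes are called by $|\Delta\beta| > 0.1$ together with a signed
diffscore gate $|s| > 13$. The commercial diffscore formula is
proprietary; it is implemented here as
$s = 10\,\mathrm{sign}(\Delta\beta)\,(-\log_{10} p)$ with $p$ from a
two-sided Mann-Whitney U test across per-sample betas. This makes the
stated equivalence "diffscore ±13 ~ adjusted p 0.05" arithmetically exact:
$10 \log_{10}(1/0.05) = 13.01$.

# Annotation and D

The promoter spans 5 kb upstream through 200 bp downstream of the TSS
(strand-aware, clipped at the chromosome start); the gene body runs from
the promoter end to the transcript 3' end. The nearest gene minimizes
|DMR midpoint − TSS| on the same chromosome, with distance ties broken by
lexicographic gene id. A DMR overlapping the nearest gene's promoter by
at least 1 bp is a promoter DMR; otherwise body if it overlaps the body;
otherwise intergenic. Promoter wins over body for straddling DMRs —
the source is silent, and promoter-first matches its promoter-centric
intersection analysis.

The relative distance is
$D = |b - \mathrm{TSS}| / L \times 100$
where $L$ is gene length and $b$ is the DMR's "end base", read here as
the DMR boundary furthest *downstream in the direction of transcription*
(right edge for + genes, left edge for − genes); a DMR ending exactly at
the TSS has $D = 0$, and $D$ can exceed 100. The "end base" wording is
ambiguous (5' vs 3' edge); the downstream reading is a documented choice
and `relativeDistance` is a standalone function if a different anchor is
wanted.

# GEM classification

Expression classes use group means of log2 values (a geometric-mean fold
change): overexpressed iff $\mathrm{log2FC} \ge 1$, under-expressed iff
$\le -1$ for the default two-fold cutoff. A gene with both hyper- and
hypomethylated DMRs *within the same compartment* is excluded before any
classification. The four canonical quadrants are promoter-hypo/over,
promoter-hyper/under, body-hyper/over and body-hypo/under; a gene
matching both a promoter and a body pattern is counted once with the
promoter pattern primary and the body pattern recorded as secondary.
The methylation-expression $r^2$ (squared Pearson correlation between
per-sample region methylation of the strongest supporting DMR and log2
expression, over tumor samples only) is descriptive by default; gating on
it (`r2Gate`) is off unless requested, since the source uses $r^2 > 0.2$
only to select heat-map rows.

# Chromatin context

A (DMR, peak) pair qualifies when the overlap is strictly greater than
50 bp (implemented as ≥ 51 bp, exposed as `minOverlap`). Overlaps are
computed with `GenomicRanges::findOverlaps` and verified against a
brute-force all-pairs oracle in the tests. Mark composition is the
fraction of DMRs per (compartment, direction) cell with a qualifying
overlap; empty cells report missing, not zero. SE/CTCF composition is
reported with both denominators (fraction of overlapping DMRs by
direction, and fraction of peaks carrying a DMR of each direction),
because the source's percentages do not state which is meant. SE/CTCF-DMR
modules come from average-linkage agglomerative clustering of per-DMR
methylation profiles on Euclidean distances, cut at `k = 3` by default
(three major modules in the motivating analysis). No 3D-contact inference
is attempted: SE-CTCF "loops" would be at most descriptive flanking
annotations, and SE stitching/ranking from raw BRD4 signal is out of
scope — SE and CTCF sets are consumed as published intervals.

# Cohort profiles

Top-variable selection ranks features by across-sample variance
(descending, ties by feature id) and keeps the top
$\lceil \mathrm{fraction} \cdot n \rceil$ (default 5%). Variance, not
MAD, is the ranking statistic — the variability measure is unstated in
the source. Sample clustering uses `hclust` with complete linkage (the
`hclust` default; the source names only "hclust"), on Euclidean
distances. PCA is centered, unscaled, with each component's sign fixed so
its largest-magnitude loading is positive. Everything that is not the DMR
ANOVA uses the two-tailed Mann-Whitney U test (exact for small untied
samples, tie-corrected normal approximation otherwise).

# The synthetic cohort

The generator emulates exactly the structure the analysis assumes:

* **Genome**: non-overlapping single-transcript genes (3-10 kb, inter-gene
  gaps over twice the promoter extent so promoter windows never collide),
  one candidate CpG cluster per promoter and per gene body, plus
  intergenic clusters placed on a disjoint 1-kb slot grid away from genes.
  Clusters carry 4-7 CpGs spaced 20-30 bp (so clusters span 60-180 bp,
  MspI-fragment scale, and always admit a >50 bp peak overlap). Body
  clusters sit in the 5' half of the body, where CpG-dense MspI fragments
  concentrate in real RRBS libraries — which also keeps the host gene the
  nearest-TSS gene.
* **Coverage**: negative-binomial per CpG and sample (mean 30, dispersion
  0.1, floored at one read). The source states no read-depth
  distribution; NB with moderate overdispersion is the standard RRBS
  model. The dispersion was fixed a priori at 0.1.
* **Methylation**: each region has a true group-level proportion (baseline
  0.30, shifted by the planted signed delta for the target group); each
  sample's region proportion is Beta-jittered around the group mean with
  concentration 300 (about 2.5 percentage points at a 30% level), and
  methylated counts are binomial. The within-patient variance of the real
  cohort is unknowable from the publication; the jitter default is a free
  parameter chosen small enough that read-sampling noise dominates — see
  the ANOVA caveat above — and is fully configurable.
* **Expression**: per-gene baseline ~ N(8, 2) on the log2 scale; planted
  GEM genes carry their signed log2 effect (default magnitude 2.0) in the
  target group; Gaussian noise with sd 0.5 — unstated in the source,
  chosen so two-fold planted effects are recoverable but not trivial.
* **Peaks**: for each (mark, direction, probability) coupling, a coupled
  peak fully covers its planted region (guaranteeing a qualifying
  overlap) with the stated probability; background peaks are uniform.

What a green recovery test establishes — and what it does not: the
generator produces unimodally distributed baselines, independent regions,
and noise exactly matching the calling model's assumptions. Real
methylomes are bimodal, spatially autocorrelated, and contaminated by
cell-composition effects; recovery at the planted effect size therefore
bounds the method's behaviour under its own model, not its field
performance. In particular, with a single 30% baseline the band filter
excludes essentially all 20-point shifts (see above), so the full
pipeline with band filtering on a default synthetic cohort calls few
DMRs; that is the filter working as specified, not a defect.

# Numerical and degenerate-input policy

* All readers reject malformed input with file and line context; no
  silent coercion.
* Internal coordinates are GRanges-native 1-based closed; BED is
  converted at the boundary; Bismark coverage positions are 1-based as in
  the format.
* Chromosome names match exactly (no "chr" aliasing); disjoint
  namespaces in overlap computations raise a warning naming both sets.
* Zero-variance regions return `NA` p-values and are excluded; zero
  denominators (empty compartments, zero DE genes) report missing, never
  zero.
* Clustering and selection tie-breaks are deterministic (feature id,
  lexicographic gene id, `hclust`'s fixed merge order), so a fixed seed
  reproduces byte-identical pipeline outputs; the run manifest records an
  md5 checksum for every emitted file.

# Known limitations

* Single-transcript gene models only; multi-isoform input is rejected.
* No smoothing-based DMR calling, beta-binomial likelihoods, or
  cell-type deconvolution.
* The CpG-replicate ANOVA is anti-conservative under strong patient-level
  methylation heterogeneity (see above); for cohorts where that dominates
  a region-level test on per-sample summaries would be preferable.
* The band filter's interaction with large effect sizes (above) means
  sensitivity analyses should treat `band` as an explicit switch.
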