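---
title: "Calling differentially methylated regions from MBD-affinity sequencing"
author: "mapdmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling differentially methylated regions from MBD-affinity sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapdmr)
```

## The measurement and the model

MBD-affinity purification sequencing (MAP-seq, also called MBD-seq) enriches
sheared genomic DNA for methylated, CpG-containing fragments before
sequencing. Read depth is therefore a proxy for local methyl-CpG density:
methylated CpG islands and other densely methylated, CpG-rich domains are
efficiently recovered, CpG-poor sequence is under-represented regardless of
its methylation state, and constitutively unmethylated islands are invisible
to the assay. Any differential analysis of such data has to respect this
enrichment structure: absolute depth is not methylation, and only regions
with robust, interpretable signal can be compared across samples.

`mapdmr` implements a complete calling strategy built around that
constraint, in five stages.

**1. Peak finding.** Per sample, maximal intervals with depth of at least
`min_depth` reads are collected; sub-threshold gaps up to `max_gap` bp
between qualifying runs are bridged, and bridged intervals shorter than
`min_length` bp are discarded. The defaults (4 reads, 90 bp, 50 bp) are
deliberately low-stringency: the goal is to delimit *where the assay
reports at all*, not to call methylation. Gaps are bridged only between runs
that each meet the depth threshold, and the length filter is applied after
bridging — the most permissive reading consistent with a low-stringency
screen.

**2. MAP-regions.** Peak sets from all samples (plus any auxiliary published
peak sets) are union-merged. Merged intervals that overlap a repeat mask by
even one base are removed entirely — repeats are where multi-mapping
artefacts concentrate, and trimming would leave fragments of dubious
interpretability (a trimming policy remains available via
`repeat_policy = "trim"`). Survivors are retained only if strictly longer
than 250 bp and containing at least two CpGs in the reference sequence, the
operational minimum for efficient MBD enrichment. The result is the
analyzable universe; everything downstream is conditional on it.

**3. Window matrix and normalization.** Each MAP-region is tiled with
abutting 50-bp windows. Terminal remainders (< 50 bp) are retained and
flagged rather than dropped: discarding them would silently remove CpGs at
region edges. Mean depth per window per sample forms the matrix. A nominal
offset of 0.1 reads is added (so ratios are always finite and positive),
each window's across-sample mean is taken as the common reference, each
sample is expressed as a ratio to that reference, and the ratio matrix is
quantile normalized so every sample shares one value distribution. Ties are
resolved by averaging tied ranks. Quantile normalization is applied to
ratios (matching the reference-ratio formulation); a `log2_scale` switch
normalizes log2 ratios instead for sensitivity analysis.

**4. Window-level inference.** Ratios are log2 transformed and each window
is fitted with a two-group means model for the contrast of interest (one
categorical variable at a time; a level can be contrasted against a named
level or against all remaining samples). The two-stage formulation
"compare each sample to the average reference, then build a secondary
between-group model" collapses algebraically to this direct group contrast
on ratio-to-reference values, because the common reference cancels in the
difference — we adopt the direct form and document the equivalence as an
assumption. Per-window residual variances are moderated by empirical Bayes:
variances are modelled as scaled chi-square draws around a scaled-inverse
chi-square prior whose parameters (`d0`, `s0^2`) are estimated by method of
moments on the log variances (trigamma inversion by Newton iteration), and
the posterior variance `(d0*s0^2 + df*s^2)/(d0 + df)` feeds a t-statistic
on `df + d0` degrees of freedom. This borrowing of strength across tens of
thousands of windows is what makes 50-bp windows testable with a handful of
samples per group. P-values are Benjamini–Hochberg adjusted across all
windows, with significance declared at adjusted P < 0.01.

**5. Knitting.** Same-direction significant windows are chained while each
successive window starts within 500 bp of the previous one; chains with at
least three significant windows become DMRs spanning the first to the last
window. Hyper- and hypomethylated windows never co-knit, since directional
DMR sets are reported separately. The anchoring of the 500-bp span is not
uniquely determined by its verbal description; we anchor start-to-start by
default and provide the end-to-start variant (`anchor = "end"`).

`mapseq_dmr()` runs all five stages and returns a classed object with
`print`, `summary`, `coef` (per-window log2 fold changes), `residuals` and
`plot` methods. `predict`/`simulate` methods are deliberately absent: the
fitted object is a per-window group contrast, for which neither has a
natural new-data semantics.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_depth` | 4 | reads | qualifying depth for peak runs |
| `min_length` | 90 | bp | minimum peak length after bridging |
| `max_gap` | 50 | bp | largest bridged sub-threshold gap |
| `min_region_len` | 250 | bp | strict MAP-region length filter (>) |
| `min_region_cpg` | 2 | CpGs | minimum reference CpGs per region |
| `window` | 50 | bp | tiling width |
| `offset` | 0.1 | reads | depth offset before ratios |
| `alpha` | 0.01 | — | BH-adjusted significance level |
| `span` | 500 | bp | knitting span (start-to-start) |
| `min_windows` | 3 | windows | minimum significant windows per DMR |

The defaults reproduce the published strategy; they are conservative by
design, trading genomic coverage for robustness of what is called.

## Downstream characterization

* `seq_stats()` / `interval_seq_stats()`: G+C fraction, CpGs per 100 bp and
  CpG observed/expected (`#CG * len / (#C * #G)`), with `N` bases excluded
  from denominators and o/e flagged missing when a sequence lacks C or G.
* `classify_annotation()`: every DMR receives exactly one category by fixed
  precedence — TSS (±500 bp), exonic, intronic, upstream, intergenic. The
  upstream window is implemented as 501–2000 bp 5′ of the TSS on the gene's
  strand, the only biologically coherent reading of the two sign
  conventions in circulation; a DMR near several genes takes the
  highest-precedence category over any of them.
* `cgi_colocalization()`: signed midpoint offsets of DMRs to the nearest
  CpG-island center within ±5 kb, with binned count and mean-level
  profiles.
* `arm_percentile_distribution()`: DMR midpoint counts relative to
  MAP-region midpoint counts in 100 percentile bins per chromosome arm,
  oriented so percentile 100 is telomere-proximal; empty bins are missing,
  never infinite. Midpoints (not base-pair coverage) define bin membership.
* `region_variance()`: per region, each sample's log2 ratio to the
  across-sample mean signal (inclusive of the sample itself — the plain
  reading of "compared to the mean of all individuals"; an exclusive-mean
  variant is available), summarized by the n−1 standard deviation.
  `variance_ranksum()` compares variance distributions by a two-sided
  Wilcoxon rank-sum test — exact when the pooled size is at most 20 without
  ties, tie-corrected normal approximation with continuity correction
  otherwise.
* `cluster_samples()` / `pca_samples()`: Euclidean complete-linkage
  clustering and centered PCA of region means, with a 0.1 signal floor and
  sex-chromosome removal before decomposition, as sample-level sanity
  checks.

## The synthetic methylome generator

Because a real MAP-seq study's headline numbers are tied to its sequencing
data, genome build and annotation tracks, validation here rests on a
generator that reproduces the *structure* of the signal:

* a genome whose background sequence is CpG-depleted (CG → CA with
  probability 0.9, giving background CpG o/e near 0.1 as in vertebrate
  genomes) at 41% G+C, punctuated by GC-rich (65%), CpG-retaining islands
  and a coordinate-level repeat mask;
* methylation states per CpG (bulk genome methylated; a configurable
  fraction of islands constitutively unmethylated and hence invisible to
  the assay; fractional states for mixtures);
* coverage built from 200-bp fragments emitted at Poisson rates
  proportional to each 50-bp bin's methylated-CpG weight, so expected depth
  is exactly monotone in methylated-CpG density. Group effects are
  multiplicative fold-changes on that weight in the affected samples;
  non-null effects define the ground-truth intervals used for scoring;
* genetic artifacts acting purely through the sequence channel: CpG-loss
  SNPs remove one methylated CpG in carriers, and Alu-like CpG-rich
  insertions add 25 methylated CpGs over 300 bp in one individual. The
  insertion is represented as a locus-level CpG gain in the shared
  coordinate system — the pipeline consumes one reference frame, and the
  false-positive mechanism (private enrichment signal with no methylation
  difference) is fully reproduced without modelling coordinate shifts.

The fragment-length distribution of the real assay is unpublished; 200 bp
is a typical sonication midpoint and is a free parameter. Per-sample
streams are seeded from the master seed and the sample id, so any sample
re-simulates bit-identically in isolation.

What the generator does *not* emulate: mappability structure beyond the
repeat mask, GC amplification bias, fragment-length variance, diploid
genotypes beyond the two artifact kinds, and spatial autocorrelation of
methylation beyond island boundaries. Passing tests therefore demonstrate
correctness of the algorithmic strategy under the stated signal model, not
robustness to every artefact of real libraries.

## Numerical choices and degenerate inputs

* The 0.1 offset guarantees strictly positive ratios; normalization refuses
  single-sample matrices (the reference would be the sample itself) and
  refuses to run twice.
* If every window has zero residual variance, moderation falls back to an
  ordinary t with an epsilon variance and warns; zero-variance windows
  among positive ones are simply shrunk to the prior.
* If the log variances show no excess dispersion over sampling noise, the
  prior degrees of freedom are infinite and all posterior variances equal
  the pooled prior — the moderated t degrades gracefully to a z-like
  statistic.
* Contrast levels with fewer than two samples are rejected (residual
  variance undefined).
* Percentile bins with no MAP-regions report missing ratios, never
  division by zero.
* Knitting ties: windows are processed in coordinate order; chains are
  deterministic functions of the significant set.

## Validation design and problem sizes

The test suite validates each operation against an independent oracle
(per-base scanning for peaks, literal step-up enumeration for BH,
exhaustive run enumeration for knitting, full enumeration of rank
assignments for the rank-sum test, closed-form least squares for the window
models, limma's empirical-Bayes fit for the moderation cross-check) and the
pipeline end to end against simulated truth: null calibration with two
groups of 10 over ~1000 regions across 20 seeds; recovery of 50 two-fold
spike-ins (25 hyper, 25 hypo) among ~1000 regions in a 10-vs-10 design over
10 seeds; a sex-dosage analog with a doubled chromosome in 7 of 43 samples;
a private CpG-rich insertion in one of three individuals profiled across
eight brain regions; and method-of-moments recovery of a known variance
prior (d0 = 4, s0² = 1) from 5000 simulated windows over 20 seeds. These
sizes keep the whole suite in the minutes range while leaving each check
statistically meaningful; `scripts/acceptance.R` recomputes all of them
from scratch.

## Known limitations

* One categorical variable per model; no covariate adjustment (the strategy
  models single biological variables, building secondary contrasts from
  reference comparisons).
* Enrichment is not corrected for CpG density or G+C content; comparisons
  are within-window across samples, where those factors cancel.
* Absolute methylation levels are out of reach of the assay; all calls are
  relative to the sample average.
* Repeat removal deletes whole intervals; signal in repeat-adjacent unique
  sequence is deliberately sacrificed.
* The rank-sum normal approximation is used above pooled n = 20; exact
  p-values with ties are not attempted.
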