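---
title: "Methods: cross-species methylation/expression analysis of RMS mouse models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species methylation/expression analysis of RMS mouse models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylGEMM)
```

## Scope and model

`methylGEMM` analyses array-style DNA methylation (beta values, the
methylated fraction at a CpG) and expression data from rhabdomyosarcoma
mouse models and human tumours. The analysis chain is: probe-level
annotation to gene regions, within-array normalization, unsupervised
clustering of the most variable probes, exact association statistics between
cluster labels and sample metadata, differential methylation/expression
calling, and direction-stratified integration across species. Every stage is
exercised end-to-end on synthetic cohorts with planted ground truth, so the
statistical behaviour of the whole chain is testable without controlled-access
data.

## Probe region annotation

A probe is assigned to a gene's **promoter** when it lies in the 1,500 bp
immediately upstream of a transcription start site or inside the first exon
(in transcription order) of any transcript of that gene, and to the **body**
when it lies in any intron or any non-first exon. Three conventions had to be
fixed where the verbal rule is silent:

- *Boundary convention.* All coordinates are 0-based half-open; the promoter
  window is `[TSS−1500, TSS)` on the plus strand and `[txEnd, txEnd+1500)` on
  the minus strand. Half-open intervals compose cleanly with BED-style
  inputs and make the window exactly 1,500 positions wide.
- *Precedence.* When transcripts of one gene disagree (one puts the probe in
  the promoter, another in an intron), the promoter wins — the "and/or" in
  the promoter definition implies promoter dominance. Assignments to
  different genes are independent: one probe may be promoter of gene A and
  body of gene B.
- *Region per (probe, gene).* At most one record per pair, so downstream
  gene-region calls never double-count a probe.

The classifier is verified against an exhaustive position-by-position oracle
over ±2 kb windows around generated transcript models, and a reflection test
(mirroring all coordinates and flipping strands) guards the strand logic.

## Normalization

Type I and type II Infinium probe chemistries have different intensity
distributions; the package implements subset-quantile within-array
normalization. Per array and channel, a random subset with equal numbers of
type I and type II probes per CpG-count category (1, 2, 3+) is drawn — the
category size being the smaller of the two types' counts — and the target
distribution is the mean of the two types' sorted subset intensities. Subset
probes map to the target by rank; all other probes interpolate linearly
between flanking subset quantiles, with the extremes clamped. The map is
monotone, so within-type ranks are preserved exactly (a tested invariant).
The subset draw is seeded; the same seed reproduces the output bit-for-bit.

Beta values are computed as `M/(M + U + 100)` (the offset regularizes dim
probes) and tests operate on M-values `log2(b/(1−b))` after clipping beta
into `[1e-3, 1−1e-3]`, which keeps the transform finite and is
variance-stabilizing relative to the bounded beta scale.

## Variable-probe selection

Probes are ranked by across-sample variance (unbiased, n−1 denominator) and
the top fraction (default 1%) or count retained. Variance was chosen over
MAD as the common default; the ranking scale is beta (configurable), and
ties break by ascending probe id so selection is deterministic. Probes with
more than 20% missing values are excluded from ranking; remaining missing
entries are mean-imputed per probe *for clustering only* — differential
testing always drops incomplete probes instead, so no imputed value ever
enters a test statistic.

## Clustering and embedding

Samples are clustered by hierarchical agglomeration (Euclidean distance,
Ward linkage — both configurable; Ward yields compact, reproducible
clusters) and cut at k = 2; the fusion-negative-like cluster is then re-cut
at k = 2, mirroring the ML/MR main split and MR1/MR2 subsets without visual
dendrogram inspection. Label orientation is fixed by metadata: the main
cluster with the larger share of high fusion expression is ML (by size when
unlabeled), and the smaller MR subset is MR1. This keeps association tables
stable across runs.

The t-SNE embedding is an exact (dense) implementation — per-sample Gaussian
bandwidths calibrated to the requested perplexity by binary search,
symmetrized joint similarities, momentum gradient descent with early
exaggeration (12× for 100 of 500 iterations, learning rate 200). The dense
O(n²) formulation is the right tool at cohort scale (tens to ~120 samples);
no approximate-neighbour machinery is needed or used. Seeded initialisation
makes coordinates reproducible; across seeds the coordinates differ but the
group separation persists (a tested property).

## Exact association statistics

Cluster–metadata associations use the conditional two-sided Fisher exact
test: with both margins fixed, p is the sum of hypergeometric point
probabilities not exceeding the observed table's probability, with a 1e-7
relative tolerance guarding floating-point ties. The implementation is
checked for exact equality against a brute-force enumeration oracle over
*every* 2×2 table with N ≤ 30, and against the reference implementation in
`stats` on random tables. Agreement between binary classifications uses
Cohen's kappa with the simple asymptotic standard error
√(P₀(1−P₀)/(N(1−Pₑ)²)) and a Wald 95% interval; fancier variance formulas
exist, but the simple one is transparent and adequate at n ≈ 30 (interval
endpoints shift by ≲0.02).

Factors constant across the contrasted samples (e.g. a mutation present in
every model) are untestable and skipped with a warning. Every emitted row
carries its 2×2 cell counts, so any p-value can be re-derived by hand.

## Differential calling and integration

Per probe, a Welch two-sample t-test on M-values (Welch, for robustness to
unequal group variances; a pooled-variance test would also be defensible)
with Benjamini–Hochberg adjustment across all tested probes, and the
conjunction rule |Δβ| > 0.2 AND adjusted p < 0.05. The effect size Δβ is
computed on the beta scale even though testing is on the M scale, matching
how methylation differences are reported in practice. Expression uses the
same machinery on log2 values with adjusted p < 0.05 (no fold-change floor
by default).

Significant probes collapse to gene-region calls: one call per (gene,
region, direction) with ≥ 1 significant supporting probe — the
supporting-probe count is always emitted so stricter multi-probe rules can
be applied downstream — and when both directions are significant in one
region both calls are emitted, flagged ambiguous. DM calls intersect with
significantly DE genes into strata (2 regions × 2 methylation × 2 expression
directions). Cross-species matching is **symbol-level** (uppercase
canonical form, or an explicit homolog map): conserved genes are reported
with their per-species strata retained rather than requiring
region/direction concordance, because a gene's regulatory geometry need not
be identical across species for the gene to be conserved. Gene-set
enrichment is the one-sided upper-tail hypergeometric (equivalent to
one-sided Fisher) against a configurable universe, defaulting to the
cross-platform reference set — genes represented by at least one probe on
both arrays — since genes absent from a platform cannot be discovered on it.

## The synthetic-data generator

The generator is first-class, tested code. It emulates the statistical
structure of the study design:

- **Cohort shape.** 31 mouse samples in three latent groups (11
  fusion-positive-like, 8 FN-Myf5-like, 12 FN-Pax7-like); a human-like
  cohort of 86 samples (38 FP / 48 FN).
- **Beta model.** Baseline per-probe means from a bimodal mixture
  (Beta(2,8) and Beta(8,2) modes); per-sample betas from a Beta distribution
  re-parameterized by (mean, precision) with precision chosen so the
  within-group SD is `noise_sd` (default 0.05) mid-range — this respects the
  [0,1] support and reproduces the array-like variance shrinkage near 0 and
  1. Planted probes get signed Δβ shifts drawn from [0.25, 0.40] (clearing
  the 0.2 calling threshold) between the stated groups, 2% of probes for the
  FP-vs-FN contrast and 1% for FN1-vs-FN2, with baselines re-anchored so the
  shifted means stay inside (0, 1); group means are clipped to
  [0.001, 0.999].
- **Expression model.** Log-normal with additive log2 shifts (default 1.5)
  on planted genes, coupled to methylation direction with probability 0.8:
  promoter hyper → under-expression and hypo → over (the repressive promoter
  convention); gene-body coupling defaults to the positive correlation
  commonly observed (hyper → over) with a configurable sign, since real
  integrated tables contain both signs.
- **Geometry.** Each gene occupies a 60 kb slot with a gene-free zone, so
  promoter windows never collide across genes; transcripts of a gene share
  the TSS and first exon, so planted regions are unambiguous. Probes are
  placed in all five categories (promoter, first exon, internal exon,
  intron, intergenic).
- **Cross-species structure.** The human cohort mirrors the mouse probe
  layout (a pretend synteny with a one-to-one probe map), adds a global
  species beta offset (default 0.15) that reproduces species-dominant
  clustering of combined cohorts, and replants FP-vs-FN effects with the
  mouse directions on a conserved core (25% of the mouse DM∩DE genes) plus a
  disjoint human-only set, so the cross-species intersection is neither
  empty nor trivially everything.
- **Determinism.** All randomness flows from one seed through fixed
  per-product substreams; regeneration is bit-identical and a golden
  checksum is under test.

What the generator does **not** emulate: realistic chromosomal CpG density
or island structure, batch effects, cell-composition heterogeneity,
probe cross-hybridization, or raw IDAT-level artefacts. Passing
parameter-recovery tests therefore demonstrates that the statistical
machinery is correct under the planted model, not that the pipeline is
robust to every failure mode of real arrays.

Within-group beta variance of real arrays is not publicly stated for this
design; `noise_sd = 0.05` was chosen once as a realistic array-scale noise
level that still leaves the planted-recovery question non-trivial, and is a
config parameter.

## Numerical choices and degenerate inputs

- Welch statistics are vectorized over matrix rows; rows where both groups
  are constant get p = 1 when the means agree and p = 0 when they differ.
- The Fisher probability-mass comparison uses a relative 1e-7 tolerance; the
  kappa error path rejects degenerate margins (Pₑ = 1).
- Selection tie-breaks, cluster label orientation, and subset naming are all
  deterministic, so repeated runs produce byte-identical outputs (the run
  manifest records per-stage checksums to make this checkable).
- p-values in association tables are additionally reported rounded to three
  decimals, the conventional reporting precision.

## Problem sizes used by the test suite

Unit tests run on reduced cohorts (4,000 probes, 600 genes) that preserve
the full group design; recovery acceptance tests run at the default study
conditions (20,000 probes, 2,000 genes, 31 + 86 samples) across three seeds.
These sizes were chosen so the planted-effect recovery questions are
statistically meaningful at array-like dimensionality while the whole suite
stays convenient to iterate on.

## Known limitations

- The two fixed fixtures of published cluster labels are *partially
  inferred*: the published composition pins the ML membership, the
  Myf5/Pax7 lineage placements and the Rb1-mutant subset placements, but the
  MR1/MR2 split of the remaining non-fusion Pax3/Myf6 tumours is not
  published and one consistent assignment was chosen (the fixture is named
  `_inferred` accordingly). Genotype-derived Ptch1 counts differ from the
  reported 9/20, and the battery reports what it computes.
- Kappa's variance formula is the simple asymptotic one; exact or
  bias-corrected intervals are out of scope.
- Moderated-variance (empirical Bayes) testing, region-based DM detection
  (bumphunting), batch correction and cell-composition correction are
  deliberately out of scope; the package tests probes and genes marginally.
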