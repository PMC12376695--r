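---
title: "Quantifying the Anthrobot life cycle: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the Anthrobot life cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(botlife)
```

Anthrobots are self-motile multicellular spheroids that self-assemble from
adult human airway epithelial cells and swim by means of outward-facing
cilia. Their life cycle has three observationally distinct phases — growth
in Matrigel, polarity reversal ("eversion") after release, and eventual
degradation — plus a marked transcriptomic departure from the progenitor
cells they derive from. `botlife` implements the quantitative analysis of
all four aspects from the two kinds of raw input such a study actually
produces: per-frame segmentation tables (centroid + area per object, the
output shape of Fiji's AnalyzeParticles) and a bulk RNA-seq counts matrix.
Because the original imaging and sequencing data are not deposited, the
package also ships generators that emulate each input with planted ground
truth, so every stage of the pipeline is testable end to end.

## Growth: lineage tracking and merge events

During the Matrigel phase a bot can form three ways: it never proliferates
(*dormant*), it expands clonally from one cell (*monoclonal*), or several
growing precursor spheroids fuse (*merger*). The discriminating statistic
is `merge_events`, defined here as the number of founding components in the
final spheroid's ancestry: 1 for dormant and monoclonal bots, *k* when *k*
founders merged. (An alternative reading — the number of merge *events*,
i.e. *k* − 1 — exists; we use the root count because it anchors monoclonal
expansion at exactly 1.)

`link_frames()` links consecutive frames by greedy mutual nearest
neighbours within `max_disp` (default 50 px — imaging is bi-daily, so
displacements are large). When two or more live tracks point at the same
particle and the particle's area is consistent with the sum of its
parents' areas, a merge node is created. The area test is relative to the
**larger** of the two quantities (tolerance `area_ratio_tol = 0.3`):
between observations the fused spheroid keeps growing, so the parent sum
systematically underestimates its area, and normalizing by the child keeps
the test symmetric under growth of up to ~40% per interval.

The other two growth features follow the area series: `fin_area` is the
area at the last trackable frame, and `sd_area` is the standard deviation
(n − 1) of consecutive differences of the *total ancestral* area per frame,
so pre-merge growth contributes variability. A figure-caption description
of `sd_area` as the "average standard deviation of area" also circulates;
we implement the consecutive-differences definition, which is the precise
one.

## Eversion: circular statistics of trajectories

After release from Matrigel the apical surface everts over ~48 h, imaged
hourly; the trajectory of the bot centroid over that window is summarized
by 14 axes: mean/median/SD of angular speed, linear distance, heading and
linear speed, plus two indices in [0, 1]:

* **straightness** = the mean resultant length $\bar R$ of the step
  headings (equivalently 1 − circular variance); 1 for a perfectly
  straight monotone path;
* **gyration** = $1 - CV(\omega)\,/\,CV(\omega \cup -\omega)$, where $CV$
  is circular variance and $\omega$ are the signed angular speeds treated
  as angles; 1 for constant-curvature (circular) motion, because then
  $CV(\omega) = 0$ while the pooled set retains spread.

Numerical conventions worth stating: headings of zero-length steps carry
the previous heading forward (leading zero-steps are dropped); angular
speeds are heading differences wrapped to $(-\pi, \pi]$, so
$|\omega| \le \pi$ and no wrap ambiguity enters the circular variance;
when $CV(\omega \cup -\omega) < 10^{-9}$ (a straight line: all
$\omega = 0$) the gyration ratio is 0/0 and the index is defined as 0, "no
gyration". Heading is summarized circularly — mean = argument of the
resultant, median = data angle minimizing mean absolute circular deviation
(ties toward the smaller angle), SD = $\sqrt{-2\ln\bar R}$ — while the
*signed* angular speed uses ordinary statistics, since its sign carries
the turning direction. A `circular_heading = FALSE` switch provides naive
linear statistics of the heading values for comparison. Frame spacing is
fixed at 1, so speeds are per frame (per hour under the emulated imaging).

## Degradation: eight area-course metrics

After week ~4 bots shrink and disintegrate. From one area series,
`degradation_features()` returns initial area, final area, their
difference and percent change, the SD and mean of successive differences,
`time_to_disintegrate` (retained frame count) and `changerate` (maximum
absolute second difference; a signed variant is available since the
observational definition — "maximum difference in the difference of
areas" — does not fix the sign). "Untrackable" is operationalized as the
area dropping below a threshold, default 5% of the initial area; the
series is truncated immediately before the first sub-threshold frame.

## Phenotype clustering

All three analyses share one stage, `phenocluster()`: z-score
standardization (constant features dropped with a warning), PCA for
reporting (deterministic sign convention: the largest-magnitude loading of
each component is positive), Ward.D2 agglomerative clustering — the
variant that takes *unsquared* Euclidean distances and merges by minimal
increase in within-cluster sum of squares — cut at a fixed *k* (3 for
growth, 2 for eversion and degradation; there is no automatic *k*
selection), and per-feature two-sided Wilcoxon rank-sum comparisons
between clusters, pairwise when *k* > 2. The exact null distribution is
used when both groups have ≤ 8 observations and no ties, the
tie-corrected normal approximation with continuity correction otherwise.
p-values map to stars with strict upper bounds: `< 0.0001` → `****`,
`< 0.001` → `***`, `< 0.01` → `**`, `< 0.05` → `*`, else `ns` (so
p = 0.05 is `ns`).

Whether the original analyses clustered raw features, z-scores or PC
scores is not recorded; we cluster on the standardized features by
default — scaling is essential because the three growth features differ
by orders of magnitude in units — and expose `cluster_space = "pca"` as
the alternative. Cluster labels are renumbered by decreasing size (ties by
smallest member index) so output is stable across runs and row
permutations.

## Transcriptome staging

The counts pipeline is deliberately implemented from first principles,
since its arithmetic is the analysis:

1. **Filter**: keep genes with CPM > 0.29 (strictly) in ≥ 3 samples,
   computed with unit factors (raw library sizes). Filtering precedes
   normalization.
2. **TMM**: reference = sample whose upper-quartile CPM is closest to the
   mean upper quartile (ties by sample id — with exactly two samples the
   choice is always a mathematical tie, so the rule matters). Per sample,
   gene-wise M (log2 ratio of count proportions vs the reference) and A
   (average log2 abundance) over genes positive in both; two-sided rank
   trims of 30% on M and 5% on A; factor =
   $2^{\sum w M / \sum w}$ with inverse asymptotic (binomial
   delta-method) variance weights; factors rescaled to geometric mean 1.
   Identical libraries give factors exactly 1.
3. **logCPM**: $\log_2\!\big(10^6 (y + p) / (N f + 2p)\big)$ with prior
   count $p = 0.5$ to keep zeros finite; with $p = 0$ this is exactly the
   textbook $\log_2(10^6 y / N f)$ on positive counts.
4. **logFC** = difference of per-condition mean logCPM; DEG sets are
   threshold sets on logFC (default > 2, one-sided for overexpression).
   Moderated differential-expression statistics (precision weights,
   empirical-Bayes shrinkage) are out of scope; a plain Welch
   t-test + Benjamini–Hochberg helper (`de_ttest()`) is included as
   clearly non-equivalent plumbing.
5. **Phylostratigraphy**: each gene carries one of 19 phylostrata (from
   "All living organisms" to "Primates"); `phylostratum_expressed_counts()`
   counts genes with mean logCPM > 1 per condition (a `measure = "cpm"`
   switch supports the alternative CPM > 1 reading of the ambiguous
   source wording), `phylostratum_deg_counts()` counts overexpressed DEGs
   per stratum. Over all 19 strata the counts partition the qualifying
   annotated genes.
6. **Morula overlap**: morula-stage genes are those with cell-averaged
   RPKM > 2; the statistic is |DEG ∩ morula| / |DEG|.

## What the generators emulate — and what they do not

Each generator is seed-deterministic and returns its planted truth.

* `gen_growth()`: dormant (constant area + noise), monoclonal (exponential
  growth, default ×1.35 per bi-daily frame over 8 frames), merger
  (founders on a circle approaching a common point, fusing when their
  equivalent-radius disks touch; fused area = exact sum). The default
  cohort (`gen_growth_cohort()`) is 16/9/5 dormant/merger/monoclonal with
  10% CV in initial area and 1.5% per-frame CV in growth rate; cohort
  mergers fuse one pair of precursors, the typical observed event.
* `gen_trajectory()`: displacers are correlated random walks (lognormal
  step lengths, meanlog log 8 px; wrapped-normal heading increments,
  SD 0.5 rad); statics are isotropic positional jitter (SD 0.8 px) around
  a fixed point. Note one consequence of that model: a static bot's step
  headings are uniform noise, so its circular heading SD is *maximal*; the
  contrast that separates the modes is displacement magnitude (and
  straightness), not heading spread. `circle` and `line` presets are exact
  geometry for analytic tests.
* `gen_decay()`: area(t) = max(0, A₀ − r·t + ε). With a shared rate,
  lifespan is increasing in A₀ — large bots live longer — which the
  degradation tests assert on a noise-free A₀ grid. The default cohort is
  26 small (800–1500 px²) and 10 large (4000–6500 px²) bots at r = 60.
* `gen_counts()`: negative-binomial counts (dispersion 0.05) with
  lognormal baselines (meanlog log 200), 10% silent genes (identically
  zero, so the expression filter's planted truth is exact), planted
  upregulation of 200 genes at log2 effect 3 in the second condition,
  lognormal per-sample depth (SD 0.15), gene lengths and stratum
  assignment (weighted toward the two ancient strata), and a morula table
  whose overlap with the planted DEG set is 13.4% by construction.

These generators reproduce the *statistical* structure the pipeline
assumes — archetype separation, mode separation, size-dependent lifespan,
planted effects with wide margins relative to sampling noise — not the
messiness of real microscopy (segmentation dropouts, debris, uneven
illumination) or real RNA-seq (gene-wise dispersion trends, batch
effects, correlated genes). Passing recovery tests therefore demonstrates
the pipeline's correctness and discriminating power under its stated
model, not performance guarantees on arbitrary real data.

## Problem sizes and verification

The shipped tests run the whole pipeline at the emulated study scale:
growth clustering on 30 bots × 8 frames, eversion on 80 trajectories × 48
steps, degradation on 36 bots, transcriptome staging on 2000 genes × 8
samples. Core numerics are verified against independent oracles: Ward.D2
linkage against an exhaustive greedy-merge implementation computing the
within-cluster sum-of-squares increase from first principles (all random
instances with n ≤ 7), circular variance against direct vector summation,
and TMM against both a naive implementation that materializes every
intermediate and, where available, the reference implementation in the
edgeR package.

```{r example, eval = FALSE}
co <- gen_growth_cohort(seed = 11)
fm <- growth_feature_matrix(co$tables)
res <- phenocluster(fm, k = 3)
res
```

## Known limitations

* Linking assumes at most modest per-interval displacement relative to
  inter-object distances; it does not handle splits (not observed in the
  emulated system), occlusion, or identity switches from crossing paths.
* The merge-area test can miss merges whose product loses substantial
  area, and 2-vs-3-founder mergers are intrinsically hard to separate by
  clustering once features are z-scored.
* Kinematics assume uniform frame spacing; there is no windowed
  ("block"-wise) variant — each bot contributes one feature vector.
* TMM reference selection between exactly two samples is a tie by
  construction; results are deterministic here but need not match tools
  that resolve the tie differently.
* DEG-by-threshold is not a significance statement; no variance
  moderation is performed.
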