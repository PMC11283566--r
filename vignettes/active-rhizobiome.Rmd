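---
title: "Methods: classifying and analyzing the active rhizobiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and analyzing the active rhizobiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizoactive)
```

## The activity model

rRNA content scales with ribosome pools and hence, loosely, with metabolic
activity, while rRNA *gene* copies count cells regardless of state. Sequencing
each sample from both DNA and cDNA therefore lets us split the observed
community, per sample, into active and non-active fractions. The procedure
implemented by `classify_activity()` is:

1. Screen reagent contaminants with `prevalence_contaminant_test()` (a
   one-sided Fisher exact test of presence in negative controls versus
   samples) and remove them, along with mitochondrial/chloroplast lineages,
   with `remove_contaminants()`.
2. Rarefy the DNA and cDNA tables to the same depth (`rarefy_assay()`),
   dropping samples below depth. Equal depth is what makes the count ratio
   interpretable without further normalization.
3. Per sample `s` and taxon `t`, compute `r = cDNA(s,t) / DNA(s,t)` and call
   the cell **active** when `cDNA > 0` and `r >= ratio_threshold`. Ties at
   the threshold are active (the criterion is "at least").
4. Resolve **phantom** cells (`DNA = 0, cDNA > 0`): a taxon whose phantom
   detections occur in more than `phantom_prevalence` of samples has those
   cells recoded to `DNA = 1` and marked `phantom_rescued` (active);
   all other phantom cells are `phantom_dropped`. The rescue acknowledges
   that a taxon repeatedly seen in cDNA libraries is unlikely to be a
   sequencing artifact even when the DNA library missed it.
5. The active community table is the DNA counts (with the 1-substitution)
   masked to active and rescued cells; downstream ecology runs on its
   relative abundances. DNA counts, not cDNA counts, carry the abundances
   because transcription varies taxon-to-taxon.

Assumptions worth keeping in mind: rRNA:rDNA ratios are an activity *proxy*
with taxon-specific scaling; a single global threshold treats all lineages
alike; and the classification is per sample, so a taxon can be active in one
sample and dormant in the next.

### Parameters

| parameter | default | units | notes |
|---|---|---|---|
| `depth` | 15 000 | reads/sample | rarefaction depth; samples below it are dropped |
| `ratio_threshold` | 1 | — | cDNA:DNA count ratio; ties active; raising it can only shrink the active set (tested property) |
| `phantom_prevalence` | 0.05 | fraction of samples | strict `>` comparison; prevalence of *phantom* detections by default (`prevalence_metric = "cdna_detection"` counts any cDNA detection instead) |
| `alpha` (decontam) | 0.05 | — | Fisher flagging threshold; flagging additionally requires control prevalence above sample prevalence |

Phantom prevalence is computed globally over the analyzed samples, after
low-depth samples are dropped (the rarefied table is the analysis universe);
a per-group run can be had by subsetting the assay before classification.
The `DNA := 1` substitution happens on the rarefied table, which is why
active-sample read totals vary from sample to sample.

## Community statistics

* `bray_curtis()` — `1 - 2*sum(min)/sum(total)` via `vegan::vegdist`; an
  all-zero sample pair is defined as distance 0 with a warning.
* `pcoa()` — Gower double-centering and eigendecomposition. Negative
  eigenvalues (non-Euclidean distances) are excluded from the coordinates
  and reported as `negative_mass`; explained variance is over the positive
  spectrum only.
* `permanova()` — sequential (Type I) sums of squares by increments of
  `tr(H G)` over the cumulative design hat matrices, pseudo-F per term,
  p-values by free row/column permutation of `G` with the `(b+1)/(B+1)`
  estimator so p is never zero. Term order is the user's; for unbalanced
  designs different orders give different partitions, which is inherent to
  sequential SS. `exhaustive = TRUE` enumerates all `n!` permutations
  (guarded to `n <= 8`) and then reports the exact enumeration p. Aliased
  terms are an error naming the term. Defaults to 999 permutations.
* `permdisp()` — distances to group spatial medians (Weiszfeld iteration,
  tolerance 1e-10; `center = "centroid"` available) in the positive-axis
  PCoA embedding, one-way F on those distances, p by permuting group labels
  against the fixed distances (the same scheme as
  `vegan::permutest.betadisper`; centers are not recomputed per
  permutation). Dropped negative-eigenvalue mass is reported rather than
  corrected — with Bray-Curtis on relative abundances it is typically a few
  percent of the spectrum.
* `phi_rg()` / `indicator_analysis()` — the abundance-based phi coefficient
  as a weighted Pearson correlation with group-equalizing weights
  `w_i = N / (K * n_g(i))`, which reduces to the point-biserial correlation
  for equal group sizes. The permutation test recomputes the *maximum* phi
  over all target sets per permutation, so the selection of the best set is
  inside the null and p-values stay honest; BH-FDR is applied across taxa
  within a run. Negative-phi "avoiders" are reported but never flagged.
  Union target sets are opt-in (`include_unions`), singletons by default.
* `anova_type3()` forces sum-to-zero contrasts before computing partial F
  tests (`car::Anova`, type III); `kruskal_wallis()`, `shapiro_w()`,
  `bh_fdr()`, and `linear_fit()` wrap the corresponding base R machinery
  behind a stable interface.

## Chemometrics

The metabolite pipeline order is fixed: `presence_filter()` (max intensity
>= 500 counts) → `iqr_filter()` (drop the lowest IQR quartile by default;
the fraction is a parameter) → `normalize_features()` (half-minimum zero
replacement per feature, log10, pareto scaling — mean-centering and division
by the square root of the SD, a middle ground between no scaling and
autoscaling for intensity data spanning decades) → `pca_scores()` or
`plsda_vip()`. PLS-DA is NIPALS PLS2 against a centered one-hot class
response, 2 components by default, convergence tolerance 1e-10;
`VIP_j = sqrt(p * sum_a SSY_a (w_aj/||w_a||)^2 / sum_a SSY_a)`, which makes
`sum_j VIP_j^2 = p` an exact identity used as a test invariant.
`top_vip_heatmap()` log-transforms the selected raw intensities, anchors any
feature whose log values dip below zero, scales each feature to [0, 1] by
its maximum, and orders rows and columns by Ward.D clustering on Euclidean
distances.

## What the synthetic generator emulates — and what it does not

`simulate_paired_assay()` draws, per crop-conditioned soil pool, log-normal
base abundances (`sdlog = 1.5`, a heavy rare tail typical of 16S surveys),
multiplies in per-sample log-normal composition noise (`sdlog = 0.3`) and
2-fold responder effects for the planted, drought, and interaction factors,
and assigns each taxon a latent activity multiplier `a_t`: log-uniform on
[1, 4] for the active half, on [0.1, 1] for the rest. The cDNA composition
is the DNA composition reweighted by `a_t` and renormalized — encoding the
premise that ratios reflect activity and making "active" well defined.
Counts are multinomial at negative-binomial library sizes (mean 25 000,
size 30), so a 15 000-read rarefaction keeps most samples while exercising
the dropping path. Phantom taxa (2%) get DNA relative abundance pinned below
`1/depth_mean` with `a_t = 25`; contaminants are extra taxa included with
probability 1.0 in negative controls and 0.05 in samples. The factorial
layout mirrors a greenhouse drought study: planted/unplanted ×
drought/watered × days 2–6 with 5 replicates, plus a watered pre-drought
baseline at day 0 and 6 negative controls.

These defaults were chosen once, at design time, by forward simulation of
candidate regimes: they put the mean percent-active in the mid-40s (the
regime such studies report), and give the ratio classifier sensitivity
~0.95 for `a_t >= 2` and specificity ~0.96 for `a_t <= 0.5` at depth
15 000. The binding constraint is counting noise on rare taxa — a cell with
one DNA read is classified from a single Poisson-scale draw — so a heavier
rare tail or a mean multiplier much above ~1.4 (which rescales every
observed ratio downward, since cDNA compositions renormalize) would degrade
both rates.

The generator does *not* emulate: sequence-level errors or chimeras, taxon
correlation structure (taxa are independent given the design), compositional
interactions beyond renormalization, overdispersed (non-multinomial)
counting noise, temporal autocorrelation within the drought time course, or
relic DNA. Passing recovery tests on these data therefore show the
*procedure* is implemented correctly and is well calibrated under a clean
generative model — not that real rhizosphere data meet these assumptions.

The metabolome generator (`simulate_metabolome()`) draws log-normal feature
intensities (log10 baselines uniform on [3, 6], within-group SD 0.3 decades)
and shifts a truth set of discriminating features between two groups by a
configurable number of SD units; feature names follow the `RT_mz`
convention.

## Numerical and design choices

* Permutation p-values use `(b+1)/(B+1)`; with 999 permutations the floor is
  0.001.
* Rarefaction subsamples without replacement (`vegan::rrarefy` behind the
  interface) under a local RNG scope, so a seed argument never perturbs the
  caller's RNG stream; DNA and cDNA tables are rarefied independently.
* Table orientation on read is never guessed silently: `"auto"` requires
  known sample ids and errors on ties — silent transposition being the
  classic amplicon-pipeline failure.
* Sample pairing accepts an explicit map file or the `__DNA`/`__cDNA` suffix
  convention; missing metadata on non-control samples is a hard error, not
  an imputation.
* Fisher's exact test (configurable alpha, default 0.05) stands in for
  composite prevalence scores in the contaminant screen: it is transparent,
  directional by construction, and exactly testable against the
  hypergeometric tail.
* Weiszfeld iteration handles coincident points by flooring distances at
  1e-12; groups of size one are rejected because their dispersion is
  undefined.
* Degenerate inputs are defined, not crashed: all-zero distance pairs,
  all-missing heatmap taxa, constant taxa in `phi_rg()` (returned as `NA`
  with the reason documented), entirely-zero metabolite features (dropped
  with a warning), all-tied Kruskal-Wallis data (`H = 0, p = 1`).

## Test problem sizes

The suite verifies the deterministic operations against independent oracles
(hand enumeration of the activity truth table, classical ANOVA F,
closed-form PCoA geometry, complete permutation enumeration at `n = 6`,
`vegan::adonis2` and `vegan::betadisper` cross-checks, the hypergeometric
tail, step-up BH arithmetic) and the stochastic properties by seeded
simulation: activity-class recovery over 10 seeds at the default design
(110 samples × 500 taxa, depth 15 000), type-I error of PERMANOVA, the
indicator test, OLS slopes, and type-III ANOVA over 200 null datasets each,
contaminant recovery over 50 seeds, indicator responder recovery over 10
seeds on a 2 × 2 × 5-replicate fixture with replicate noise `sdlog = 0.2`
(chosen so the 2-fold effect sits ~3.5 SD above the noise, where the
permutation floor is reachable under BH across 100 taxa), and VIP recovery
over 10 seeds. These sizes keep the full suite around half a minute while
leaving each calibration interval informative.

## Known limitations

* The ratio threshold is global; lineage-specific rRNA operon copy numbers
  and transcription rates are not modeled, so cross-taxon comparisons of
  activity remain qualitative.
* PERMDISP drops imaginary PCoA axes instead of applying the full
  imaginary-part correction; the dropped eigenvalue mass is logged so users
  can judge the distortion.
* PERMANOVA reports sequential SS only; marginal (Type II/III)
  partitioning for distance matrices is out of scope.
* BIOM support covers what `biomformat` parses; HDF5 BIOM requires that
  package's HDF5 stack.
* Weighted UniFrac is not provided — it requires a phylogeny, which the
  package deliberately does not handle.
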