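---
title: "Classifying case-control cohorts from whole-blood miRNA microarrays"
author: "mirscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying case-control cohorts from whole-blood miRNA microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirscreen)
```

## The problem

Ovarian carcinoma is usually detected late, and no single serum marker
(CA125 included) is sensitive and specific enough for population
screening. An alternative strategy profiles microRNAs in peripheral
blood: miRNAs are stable, measurable in the cellular blood fraction, and
hundreds can be read out in parallel on a microarray, so a *pattern* of
markers can be learned instead of thresholding a single analyte.

`mirscreen` implements the complete statistical workflow of such a
study, from probe-level array data to screening arithmetic:

1. a **synthetic cohort generator** that emulates a Geniom-style array
   (904 miRNA/miRNA\* probes, 7 replicate spots per probe per sample)
   with planted, known group effects;
2. **preprocessing**: background correction, median summarization of the
   replicate spots, and glog (arsinh) variance-stabilizing
   normalization;
3. **per-miRNA inference**: Shapiro–Wilk normality screening, unpaired
   two-tailed t-tests, Benjamini–Hochberg FDR adjustment, ranked top-k
   tables, and single-marker ROC/AUC;
4. a **classification engine**: repeated stratified 10-fold
   cross-validation of SVMs with a t-test feature filter recomputed
   inside every training fold, plus permutation-null validation;
5. **screening arithmetic**: PPV/NPV as functions of sensitivity,
   specificity and prevalence, and the inverse problem (the prevalence a
   risk population must have for a target PPV).

Because public probe-level data for such cohorts are generally not
available, the generator is a first-class, tested component: every
downstream stage is validated against cohorts whose truth is known.

## The generative model

For probe $i$, sample $s$ and replicate spot $r$ the generator draws, on
the glog intensity scale,

$$z_{is} = \beta_i + \delta_i \, \mathbb{1}[s \in \text{case}] +
  b_{is}, \qquad
  z_{isr} = z_{is} + \varepsilon_{isr},$$

with probe baselines $\beta_i \sim N(\mu_0, \sigma_\beta^2)$, planted
effects $\delta_i \in \{0, \pm\delta\}$, biological noise
$b_{is} \sim N(0, \sigma_b^2)$ and spot noise
$\varepsilon_{isr} \sim N(0, \sigma_\epsilon^2)$. The raw-scale spot
intensity is

$$y_{isr} = e^{a_s} \sinh(z_{isr}) + \mathrm{bg}_{isr},$$

where $a_s \sim N(0, \sigma_a^2)$ is a per-array multiplicative effect
(removed again by normalization) and $\mathrm{bg}_{isr}$ an additive
raw-scale background draw. All randomness flows from one integer seed,
and identical configurations reproduce bit-identical cohorts.

Planting the effect additively on the glog scale makes effect sizes
directly interpretable in the space where the t-tests and the SVM
operate; a 2-glog-unit effect is a "strong" marker relative to the
calibrated per-sample noise (sd ~0.05, see below). Background is
additive on the raw scale, per spot, which is why the preprocessing
chain subtracts it before summarizing. Case samples receive histological
subtype labels (serous/endometrioid/solid in realistic proportions) but
subtypes carry no distributional difference by default; they exist as a
hook for heterogeneity experiments.

### Calibrating the noise to observed replicate quality

Whole-blood Geniom arrays have been characterized by two replicate
statistics: a Pearson correlation of about **0.85** between biological
replicate profiles and a variance of about **0.005** of their per-probe
differences, both on the processed scale. `calibrate_noise()` tunes the
generator to reproduce these numbers *after the full preprocessing
chain*, by deterministic Monte-Carlo bisection on simulated replicate
pairs.

Two points deserve honesty:

* **Identifiability.** Because the median over the 7 spots shrinks the
  spot noise by a fixed factor $k$, both replicate statistics depend on
  the same combination
  $w = \sigma_b^2 + k\,\sigma_\epsilon^2$ (the difference variance is
  $\approx 2w$; the correlation is
  $\sigma_\beta^2 / (\sigma_\beta^2 + w)$). The pair of targets
  therefore pins down $w$ and the baseline spread $\sigma_\beta$, not
  the spot/bio split. The split is fixed by convention — equal variance
  contributions — and the implied $\sigma_\beta$ is returned and frozen
  alongside the two noise sds (`calibrated_noise_defaults`).
* **What the targets imply.** A replicate correlation of 0.85 jointly
  with a difference variance of 0.005 forces a small baseline spread
  ($\sigma_\beta \approx 0.13$ glog units) under this Gaussian model:
  if probe baselines varied as widely as raw intensities suggest,
  replicate profiles would correlate near 1. The generator accepts the
  printed statistics at face value; its cohorts are correspondingly
  compressed in dynamic range compared to real arrays.

The calibration is performed once per targets; the package defaults are
the frozen result for (0.85, 0.005), verified in the test suite over
1000 fresh replicate pairs. Whether such replicate statistics are
computed before or after normalization is usually not documented for
real data; this package defines them after the full chain, which is the
scale all downstream analysis uses.

## Preprocessing

* **Background correction** subtracts the per-spot background estimate
  and floors at the 1st percentile of positive corrected values (at
  least 0.5), keeping the glog argument positive without distorting the
  bulk of the data. A corrected set refuses to be corrected again.
* **Summarization** takes the median of the replicate spots — robust to
  a single aberrant spot per probe (a 7-spot probe tolerates up to 3).
* **Normalization** follows the variance-stabilization idea: each array
  is calibrated to a robust reference profile (the probe-wise median
  across arrays) by an affine map fitted with iteratively reweighted
  least squares (Huber loss), then transformed with
  $\operatorname{arsinh}(\cdot / c)$, $c = 1$ by default. The robust
  fit tolerates a minority (≲30%) of deregulated probes; the arsinh
  behaves like a log for large intensities and linearly near zero, so
  measurement variance is approximately intensity-independent
  afterwards (the suite checks a max/min decile-variance ratio below
  3). Full maximum-likelihood VSN estimates the affine parameters and
  transform jointly; the calibrate-then-transform factorization used
  here keeps both essential properties (between-array calibration,
  variance flattening) with a deterministic, dependency-light fit, and
  the downstream engine depends only on rank/variance behavior, not on
  a particular likelihood. Normalization is fitted on summarized (not
  spot-level) values; since the median commutes with monotone
  transforms this choice only affects how spot noise enters the
  calibration, and the noise calibration absorbs it.

## Per-miRNA inference

The normality screen (Shapiro–Wilk per probe per group) is advisory: it
reports the passing fraction but never gates the t-tests, since
exclusion rules are rarely published and silent gating would make
results irreproducible. The t-test defaults to the Welch
(unequal-variance) form — the safer default — with the pooled Student
form selectable, as published analyses of this kind usually do not say
which was used. Benjamini–Hochberg adjustment is the standard step-up
procedure (delegated to `stats::p.adjust`; an independent brute-force
implementation cross-checks it in the tests). The DE table sorts by
ascending p-value with a documented deterministic tie-break (larger
|t|, then probe id), reports the direction as the sign of the
case-minus-control glog mean difference, and keeps the counts of
unadjusted and adjusted significant probes.

ROC curves sweep one threshold per distinct score; AUC is the
trapezoidal integral, which equals the Mann–Whitney pairwise statistic
(ties counted half) — the package carries both implementations and the
suite asserts their equality on random inputs, plus agreement with
pROC. Orientation is explicit and never auto-flipped: an AUC below 0.5
is information, not an error.

## The classification engine

The engine follows the published design for blood-profile
classification: `n_repeats` repetitions (default 100) of stratified
10-fold cross-validation; in each training fold the `s` probes with the
lowest t-test p-values are selected — *using the training fold only* —
and an SVM (`e1071`) is trained per (subset size, kernel, cost) grid
cell, with kernels linear/polynomial/sigmoid/radial and cost in decimal
powers 0.01–10. Held-out predictions are pooled per pass into one
confusion matrix; per-cell metrics are averaged over repeats; the best
cell maximizes mean accuracy with deterministic tie-breaks (smaller
subset, kernel order, smaller cost).

Design choices worth recording:

* **Stratification** is on by default: with 15 controls and 10 folds an
  unstratified split can produce folds without controls. The fold
  assigner deals each class round-robin over a shuffled fold order,
  placing leftovers of successive classes on disjoint folds, so fold
  sizes differ by at most one and class ratios per fold by at most one
  sample.
* **Pooling**: metrics are pooled over the folds of a pass (one
  confusion matrix per pass), then averaged over repeats. Averaging
  per-fold rates instead would weight small folds up; with 39 samples
  the difference is minor but the pooled form satisfies the exact
  identity $\mathrm{acc} = (\mathrm{sens}\cdot n_{case} +
  \mathrm{spec}\cdot n_{ctrl})/n$, which the suite asserts.
* **Subset-size grid** defaults to {10, 20, 40, 60, 100, 200}, a
  reasonable sampling "according to the included number of miRNAs".
* **Permutation null**: each permutation run draws one fresh label
  permutation (class sizes preserved) and re-executes the full
  engine — fold assignment, in-fold re-ranking, training, prediction —
  under it; re-ranking inside folds is required for a valid null. The
  empirical exceedance is $(\#\{perm \ge obs\} + 1)/(runs + 1)$. Fold
  assignments are re-drawn per run rather than frozen; with the filter
  re-run under permuted labels the two conventions are equivalent in
  distribution.
* **Leakage probe**: `leakage_probe()` runs the engine twice, once
  correctly and once with the filter deliberately applied to all
  samples before cross-validation. On effect-free data the leaky
  variant's accuracy exceeds the correct one by a wide margin (~0.4 on
  a 904-probe null cohort) — the selection bias the in-fold filter
  exists to avoid, kept in the package as a permanent self-test.

## Screening arithmetic

`ppv()`, `npv()` and `prevalence_for_ppv()` are exact Bayes-rule
expressions. An annual incidence quoted as 40 cases per 10^5 women is
treated as the prevalence of a single annual screen — the only reading
under which a sensitivity-86.7%/specificity-88.1% test drops to a PPV
of 0.3% in the general population while retaining an NPV above 99.9%.
The inversion is closed-form and round-trips through `ppv()` to
1e-12. Values are carried at full precision; percent rounding (one
decimal) happens only in reporting.

## Problem sizes and determinism

The test suite exercises the full 904 × 7 × 39 design where the claim
depends on it (array structure, replicate calibration over 1000 pairs,
null-cohort type-I error, leakage over 20 seeds, planted-marker
recovery over 20 seeds, and a 20-repeat/100-permutation classification
run); unit tests of individual operations use smaller cohorts (tens of
probes, 10–20 samples) chosen so each file runs in seconds. Every
stochastic component takes an explicit integer seed and restores the
caller's RNG state; identical seeds give bit-identical outputs, which
the suite asserts for the generator, the folds, the CV report and the
pipeline manifest checksums.

## Limitations

* The generator is Gaussian on the glog scale with independent probes;
  real arrays show correlated probe blocks, heavy-tailed outliers,
  batch effects between labeling protocols, and subtype heterogeneity.
  Passing tests demonstrate the *machinery* (no leakage, calibrated
  nulls, parameter recovery), not that real cohorts are this easy.
* The normalization is a robust-affine + arsinh factorization, not the
  full VSN likelihood; its parameters are not interchangeable with
  published VSN fits.
* Real-data headline numbers from blood-profile studies (e.g. accuracy
  76.3% for a 24-vs-15 ovarian-cancer cohort, or below-chance permuted
  accuracies around 40%) depend on the original raw profiles, which
  have no public accession; they characterize the application, and this
  package makes no attempt to reproduce them.
* No AUC confidence intervals, no nested hyper-parameter tuning beyond
  the reported grid, no multi-class support, no cost-effectiveness
  modeling.
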