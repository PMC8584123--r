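---
title: "Models and methods behind coexpose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coexpose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexpose)
```

# The design and its statistical problem

coexpose targets 2×2 factorial exposure experiments: control (CTL), a
chemical agent alone (BPA), a physical agent alone (RAD), and the
combination (BPA_RAD). The transcriptomic arm of such studies often runs
on pooled material with only two replicates per condition. With N = 8
arrays and four groups there are d = 4 residual degrees of freedom per
gene — far too few for stable gene-wise variance estimates. Every method
in this package is shaped by that constraint.

# Moderated differential expression

## Model

Per gene g, log2 intensities are modeled as group means plus normal
noise, `y_gij = mu_gj + e_gij`, `e ~ N(0, sigma_g^2)`, with the
hierarchical variance prior

    sigma_g^2 ~ s0^2 * d0 / chisq(d0)

(a scaled inverse-chi-square distribution). The group-means (one-way,
four-level) parameterization is used rather than an explicit two-factor
interaction coefficient; the fitted cell means are identical either way,
and all downstream quantities are contrasts of cell means.

## Estimation

`fit_groups()` computes cell means and the pooled within-group variance
s² on d = N − 4 df. `estimate_prior()` fits (d0, s0²) by the method of
moments on log variances: under the model, `log(s²)` has mean and
variance expressible through digamma/trigamma functions of d/2 and d0/2,
so matching the first two empirical moments gives a closed-form
estimator (the trigamma inverse is obtained by a short Newton
iteration). When the spread of `log(s²)` does not exceed what chi-square
sampling alone explains, the excess-dispersion moment is nonpositive;
the estimator then returns d0 = ∞ with s0² equal to the mean of the
positive variances — the one-shared-variance limit. Genes with s² = 0
(possible at n = 2) are excluded from the moments but still receive a
positive posterior variance through s0², so no statistic is undefined.

`moderated_contrast()` tests each exposure against control with
t = logFC / sqrt(s̃²(1/n_t + 1/n_c)) on d + d0 df, where
s̃² = (d0·s0² + d·s²)/(d0 + d). Two limits anchor the implementation:
d0 = ∞ gives the known-variance z-test, and d0 = 0 the ordinary
pooled-error contrast t-test; both are asserted in the test suite. A
moderated F across the four groups is exposed (`moderated_ftest()`) but
DEG calls always use the per-contrast t, matching the volcano-style
per-contrast reporting this pipeline is built for.

## Thresholds

DEGs are |logFC| ≥ 0.5 and p ≤ 0.05, both inclusive, on **raw**
p-values; this mirrors the filtering convention of the motivating study
design. A Benjamini–Hochberg column is written into every DE table for
transparency but never enters the filter. Contrasts are always exposed
minus control, so negative logFC means downregulation.

# Interaction classification

For each misregulated transcript the ratio
r = |logFC(combo)| / |logFC(BPA) + logFC(RAD)| is compared to the
additivity window [0.8, 1.2]. Three genuinely open points were resolved
as follows:

* **Boundary ownership.** The printed threshold rules overlap at exactly
  0.8 and 1.2. The additive class owns the closed interval;
  potentiation and antagonism are open. This preserves the additive
  window verbatim and makes the classification total and exclusive
  (property-tested on grids that hit both boundaries exactly).
* **The "unexpected" class.** r is unsigned, so a combined response
  pointing opposite to the predicted sum would otherwise be classified
  by magnitude alone. A transcript is "unexpected" when
  sign(logFC_combo) ≠ sign(logFC_BPA + logFC_RAD) (a zero combined
  response counts as concordant) or when the predicted sum is
  numerically zero (|sum| < 1e-8, far below any meaningful logFC
  resolution) and r is therefore undefined.
* **The universe.** The default universe is the union of significant
  DEGs over all three contrasts. The restriction to single-exposure DEGs
  only is available as `universe_mode = "bpa_rad_only"`; class
  percentages are always taken over the universe size.

Classification is scale-invariant: multiplying all three logFCs by a
positive constant changes neither r nor the class.

# Gene-set median-shift test

Given the unfiltered per-gene logFC vector for one contrast, the test
draws 1000 random sets of 200 genes (simple random sampling without
replacement within a set, independent across sets, per contrast), takes
the median of each, and compares the observed set median against that
null. Two p-values are reported:

* the **one-sample t-test** of the null medians against the observed
  median as reference constant — the procedure as practiced, kept as the
  headline number; with n = 1000 "observations" it is anti-conservative
  when the observed median is even slightly off-center;
* the **empirical rank p-value** `(#{|null − mean(null)| ≥ |obs −
  mean(null)|} + 1)/(n_sets + 1)`, which is calibrated by construction
  and bounded below by 1/(n_sets + 1) ≈ 0.001.

Both are two-sided; a direction (up/down) is only called when p < alpha.
Unmeasured set members are dropped (and counted), never imputed. A
zero-variance null (all medians identical, e.g. a constant logFC field)
degenerates to p = 1 with a warning rather than an error.

# Endpoint statistics

* **Abercrombie correction** N = n·T/(T+H): T (section thickness) and H
  (mean nuclear height) are explicit user inputs in micrometers, since
  they are microscopy-protocol constants not recoverable from counts.
  The factor is 1 at H = 0, 1/2 at H = T, monotone decreasing in H, and
  invariant under joint rescaling of T and H.
* **Whole-organ extrapolation** multiplies the summed corrected counts
  by the sampling interval k (equidistant 1-in-k section sampling); k is
  an input because protocols state the number of sections counted, not
  the organ's total.
* **Two-way ANOVA + Tukey.** value ~ bpa * rad with type-II sums of
  squares (`car::Anova`), appropriate for balanced or near-balanced 2×2
  tables. Tukey HSD runs on the four cell means (not factor margins)
  because figure letters annotate condition bars; the compact letter
  display is computed by the insert-and-absorb algorithm and satisfies
  letters-shared ⇔ not-significant by construction (and by test against
  `multcomp::cld`). An all-constant table short-circuits to p = 1 and a
  single shared letter instead of 0/0 F statistics.
* **Preference score** (a − b)/(a + b), antisymmetric, undefined (error)
  only when no time was spent in either arm. The chi-square test
  sometimes quoted alongside this score lacks a stated contingency
  construction and is deliberately not implemented.

# The synthetic-data generator

`simulate_expression()` draws baselines `N(7, 1.5)` (typical log2
microarray intensity location and spread), variances from the scaled
inverse-chi-square prior, and plants effects:

* independent Bernoulli(0.05) selection of responsive genes per single
  exposure — overlap between the two DEG lists arises by chance;
* effect magnitudes uniform on [0.5, 2] (detectable by construction:
  the lower bound equals the DEG logFC cutoff), signs ±1 equiprobable;
* each responsive gene draws an interaction class from
  `interaction_mix` (default uniform) and gets its combined effect as
  sum × {1, 2.0, 0.4, −1} for additive / potentiation / antagonism /
  unexpected. The factors 2.0 and 0.4 sit well clear of the 1.2 / 0.8
  decision boundaries — a deliberately recoverable planted truth;
* a planted 200-gene set whose members all carry the same combined
  shift (−0.5, split evenly between the two single effects, hence
  additive), emulating a coherently downregulated steroidogenesis-like
  signature whose true set median equals the configured shift exactly.

One integer seed drives a single RNG stream (`withr::with_seed`), so
identical configs are bit-identical and the global RNG state is never
touched.

**What the generator does not emulate:** probe-level effects, RMA
preprocessing artifacts, array spatial effects, correlated noise between
genes (beyond the planted set's mean shift), annotation error, or the
variance consequences of pooling five exposures per sample — each pool
is treated as one independent sample, because the pooling scheme's
variance structure is not identifiable from the published design.
Passing recovery tests therefore demonstrates correctness of the
statistics under the stated model, not robustness to those real-data
features.

# Problem sizes and numerical choices

The validation suite runs at desk scale, chosen to keep each check
statistically decisive: 20,000 genes for null calibration and prior
recovery (binomial s.e. of the type-I rate ≈ 0.0015), 5,000 genes for
class-recovery and gene-set power runs, 1000 random sets / 1000
replicate draws for resampling checks, 1000 simulated tables for the
Tukey letter contract, and a ≥ 10⁵-triple grid (with the exact boundary
ratios ±0.8, ±1.2 included) for classifier–oracle equivalence. Class
recovery is evaluated with the planted coherent set disabled: its
members carry half-size single effects (−0.25) below the detectability
bound that the recovery conditions assume, and it answers a different
question (set-level shift detection) than per-gene class recovery.

Other numerical decisions: the zero-denominator guard for r is 1e-8;
moderated p-values at zero posterior variance with nonzero logFC are 0
with a warning (never an exception); TSV is used throughout because gene
ids and set names may contain commas; and every pipeline output is
written deterministically so that rerunning with the same config and
seed yields byte-identical tables.

# Known limitations

* The moderated model assumes common variance across the four groups of
  a gene; exposure-dependent variance is not modeled.
* With two replicates per group, individual logFC estimates have
  standard error ≈ sigma; class calls near the additivity boundaries
  are intrinsically noisy, which is why recovery is assessed on planted
  truths with well-separated factors.
* The t-based shift-test p-value is anti-conservative by design
  fidelity; use the rank p-value for calibrated inference.
* No enrichment-database access, probe summarization, batch correction
  or annotation mapping: the pipeline starts at a normalized expression
  matrix and user-supplied gene sets.
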