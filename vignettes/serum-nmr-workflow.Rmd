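---
title: "Serum 1H-NMR metabolomics: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum 1H-NMR metabolomics: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nmrmet` implements a complete serum ^1^H-NMR metabolomics workflow for a
three-group colorectal study design (healthy controls, colorectal polyp
patients, colorectal cancer patients): spectral binning and normalization,
latent-variable classification with validation, differential-metabolite
calling, and ROC-based biomarker ranking. Because no public serum cohort
accompanies this design, the package ships a synthetic-spectrum generator
that reproduces the statistical structure the analysis assumes; every stage
is exercised against cohorts whose ground truth is known.

```{r, eval = FALSE}
library(nmrmet)
res <- run_pipeline(pipeline_config(seed = 1))
res
```

## The synthetic cohort generator

`simulate_cohort()` renders frequency-domain CPMG-style serum spectra on a
uniform grid of 0.0005 ppm from -0.05 to 9.05 ppm (the margins keep the
0-9 ppm analysis window covered after referencing shifts). Each of the 23
metabolites in the packaged reference table contributes Lorentzian
multiplets at its literature chemical shifts:

* Doublets, triplets and quartets are drawn as 2/3/4 lines with binomial
  intensity ratios (1:1, 1:2:1, 1:3:3:1) at a fixed 0.012 ppm spacing; a
  J-coupling value is not part of the reference data, so one representative
  proton-proton splitting at 600 MHz is used throughout.
* Sharp lines use a full width at half maximum of 0.002 ppm; multiplet
  envelopes (`m`) and broad signals (`bra`) use 0.02 ppm. These reproduce
  realistic CPMG serum line widths while keeping multiplets resolvable at
  the 0.001 ppm bin width.
* Per-sample metabolite concentrations are drawn log-normally
  (`sdlog = 0.15`) around the group mean, so group fold changes act
  multiplicatively, the standard model for metabolite abundances.
* Group means are the reference base concentration times a group
  multiplier derived from the polyp-vs-control and CRC-vs-control effect
  records (fold for "up", 1/fold for "down"). The CRC-vs-polyp effect
  column is internally inconsistent with the two vs-control columns for a
  few metabolites (glutamate, serine, lysine) and is therefore used only as
  the planted-direction reference for that comparison, never to construct
  group means.
* A broad residual-water hump (Lorentzian, centre 4.85 ppm, FWHM 0.15 ppm),
  a gently sloping random per-sample baseline, a single global per-sample
  chemical-shift jitter (`sd` 0.002 ppm, emulating miscalibration that
  referencing corrects), and additive Gaussian point noise complete each
  spectrum. Intensities are clipped at zero, matching magnitude-mode
  spectra; the clipping is negligible wherever baseline plus signal
  dominates the noise.

Default cohort sizes are 38 controls, 32 polyp and 40 CRC samples (110
spectra). What the generator does *not* emulate: time-domain acquisition
and apodization, phase and baseline distortion, pH-dependent shift changes,
peak-shape asymmetry, and inter-metabolite correlation beyond the planted
group structure. Passing tests therefore demonstrate that the analysis
recovers structure of this kind when present; they do not certify
performance on real sera, whose overlap and baseline behaviour are harsher.

Base concentrations are fixed, plausible relative serum levels (glucose and
lipid largest, amino acids intermediate); no single metabolite exceeds
about a sixth of the total integrated signal, which keeps total-intensity
normalization from inverting weak planted directions.

## Preprocessing

`reference_to_lactate()` aligns each spectrum so the lactate CH~3~ doublet
sits at exactly 1.330 ppm. Detection uses a matched two-Lorentzian filter
over a +/-0.05 ppm search window; ties break toward the smaller shift, and
windows without a clear peak (maximum below median + 5 MAD) raise an error
naming the sample rather than passing silently.

`bin_spectra()` segments 0-9 ppm into 9000 half-open `[left, right)` bins
of 0.001 ppm. The left-closed convention and the bin value — trapezoidal
integral over the bin divided by the width, i.e. mean intensity — are
package choices; binning is exactly linear in the input spectra.
`exclude_water()` masks the 500 bins whose centres fall in [4.6, 5.1) ppm;
masked bins are dropped from normalization and modeling, never
zero-filled. `normalize_total()` rescales every sample so its active bins
sum to one. Exclusion is applied before normalization, so the suppressed
water region carries no weight in the constant-sum constraint; the
alternative order would let residual water artifacts leak into every other
bin's normalized value.

## Latent-variable models

All models mean-centre and unit-variance scale the active bins (the common
default of commercial chemometrics software); Pareto and centre-only
scaling are available. PCA uses the singular value decomposition with a
deterministic sign convention (largest-magnitude loading element positive).

PLS-DA is NIPALS PLS1 against the 0/1 class vector with X and y deflation.
OPLS-DA first strips components of X-variation orthogonal to the class
vector (one by default; the appropriate count is data-dependent and can be
raised), then fits a single predictive component tp1. With zero orthogonal
components OPLS-DA coincides exactly with one-component PLS-DA, and the
orthogonal scores have zero covariance with the class vector by
construction — both are tested invariants. The predictive score is oriented
so the alphabetically second class has positive mean tp1.

`cross_validate()` computes `Q2 = 1 - PRESS/SS` from stratified 7-fold
cross-validation with seeded fold assignment. `permutation_test()` refits
under 200 label permutations by default, reports R2Y/Q2 intercepts of the
regression against the permuted-label correlation, and an empirical
p-value `(1 + #{Q2_perm >= Q2_obs}) / (n_perm + 1)`, which is exactly
calibrated by construction. `cv_anova()` implements the cross-validated
ANOVA F-test (`SS - PRESS` on A model degrees of freedom against PRESS on
`n - A - 1`); when cross-validated predictions do no better than the class
mean it reports p = 1. On null data this test is conservative — most null
fits have `PRESS >= SS`, so its type-I error sits well below the nominal
level. That conservativeness is a property of the statistic itself and is
deliberately not "corrected".

`vip()` implements the standard weight-based importance whose squares
average to one; `correlation_loadings()` gives the Pearson correlation of
each bin with tp1 (zero-variance bins report 0 with a flag).

## Differential metabolites

Significance thresholds for the correlation loadings come from the Student
t distribution: with df equal to the smaller group size minus one,
`critical_r = t_c / sqrt(t_c^2 + df)`. For the default design this yields
0.344/0.442 (polyp vs control) and 0.316/0.408 (CRC vs control) at
alpha = 0.05/0.01. A bin is very significant when VIP > 1 and |r| exceeds
the 1% threshold, significant between the 5% and 1% thresholds, and not
significant otherwise — the VIP rule dominates.

Metabolite relative concentrations are sums of normalized bin values over
signature windows (peak centre +/- 0.01 ppm) restricted to peaks flagged
clean in the reference table; overlapping resonances (leucine/isoleucine/
valine methyls, the crowded 3.5-4.0 ppm sugar region) are resolved by
assigning each metabolite a peak unique to it. Metabolite-level VIP and r
are taken from the maximum-|r| bin inside the windows, since a single pair
per metabolite must represent many bins and no aggregation rule is forced
by the reporting convention. Fold changes are ratios of group means
expressed >= 1 with a separate direction flag (so decreases also show
folds above one), and the univariate p-value is a two-sided Mann-Whitney
test — robust to the non-normality of normalized intensities; means rather
than medians define the fold to match the usual reporting convention.

## Biomarker analysis

`roc_curve()` sweeps thresholds over the observed values, computes the
trapezoidal AUC (identical to the tie-corrected concordant-pair count),
orients the score so AUC >= 0.5 with the polarity recorded, and reports
the cutoff maximizing the Youden index. `multivariate_roc()` follows the
Monte-Carlo scheme popularized by web biomarker modules: 100 stratified
2/3:1/3 splits; per split a 500-tree random forest ranks features by mean
impurity decrease, the top five are kept, a second forest is fitted, and
held-out class probabilities are pooled by per-sample averaging into one
ROC plus a selection-frequency ranking (ties alphabetical).
`ratio_feature()` builds metabolite-ratio marks such as acetate/glycerol
and lactate/citrate, and `svm_validate()` checks a feature set with a
linear SVM on a disjoint validation cohort, refusing overlapping sample
ids.

## Numerical and degenerate-input behaviour

Binning requires the spectrum axis to cover the requested region and the
width to divide it integrally; all-zero samples fail normalization with
the sample named; fitting requires two classes with at least two samples
each; fold counts above the smallest class size are refused; quantification
windows that fall entirely inside the water mask raise an error for that
metabolite. Every stochastic step (cohort draw, fold assignment,
permutations, Monte-Carlo splits) takes an explicit seed, and a fixed seed
reproduces results byte for byte.

## Problem sizes used in the test suite

The shipped tests run the full 9000-bin pipeline at the default 110-sample
design for the end-to-end checks, 60 samples per group for
direction-recovery, 200 per group for fold-change recovery, 50 replicate
cohorts for the ratio-AUC ordering check, and 200 replicates of a 40-sample,
10-variable null design for the calibration study — sizes chosen to give
stable Monte-Carlo estimates for each property while remaining quick to
run.

## Known limitations

* Pairwise two-class models only; no multi-class PLS variants.
* Global referencing only — no per-peak alignment or baseline correction,
  which real sera generally need before binning.
* One representative J-splitting and two line widths; no second-order
  multiplet structure.
* Pathway-level interpretation of the differential metabolites is out of
  scope.
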