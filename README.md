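# nmrmet

Serum ^1^H-NMR metabolomics for a three-group colorectal design — healthy
controls, colorectal polyp patients and colorectal cancer (CRC) patients —
as a tested, reproducible R pipeline. The package is aimed at metabolomics
analysts who want the standard chemometrics workflow (binning → OPLS-DA →
VIP/correlation significance → biomarker ROC) as plain, seedable R
functions rather than point-and-click software, together with a synthetic
serum-spectrum generator so every stage can be validated against known
ground truth.

## What it computes

* **Preprocessing.** Spectra are referenced to the lactate CH3 doublet at
  δ1.33 ppm, the region δ0–9 ppm is segmented into 9000 bins of 0.001 ppm
  (bin value = mean intensity over the bin), the suppressed-water region
  δ4.6–5.1 ppm is masked (500 bins), and each sample is normalized to unit
  total intensity.
* **Chemometrics.** PCA, PLS-DA and OPLS-DA (NIPALS) on the scaled bin
  matrix. OPLS-DA removes X-variation orthogonal to class membership and
  concentrates the class contrast in one predictive component tp1; models
  report R²X, R²Y and the stratified 7-fold cross-validated Q². Validation
  by response permutation testing (RPT, with R²Y/Q² intercepts and an
  empirical p-value) and by CV-ANOVA (F-test of cross-validated residuals).
* **Differential metabolites.** Variables are called by the joint rule
  VIP > 1 and |r| above the critical Pearson correlation

      r_c = t_c / sqrt(t_c^2 + df),   df = min(n1, n2) - 1,

  with t_c the two-tailed Student-t critical value (α = 0.05 / 0.01).
  Metabolite relative concentrations are window integrals of the
  normalized spectrum; the differential table reports VIP, r, significance
  class, fold change (≥ 1 with a direction flag) and a Mann–Whitney
  p-value per pairwise comparison.
* **Biomarkers.** Monte-Carlo multivariate ROC (repeated stratified 2/3
  splits, random-forest feature ranking, top-5 classifier, pooled
  probabilities), metabolite-ratio diagnostics (acetate/glycerol,
  lactate/citrate) with trapezoid AUC and Youden cutoffs, and a linear-SVM
  check on held-out cohorts.

Because no public serum cohort accompanies this design, `simulate_cohort()`
generates CPMG-style spectra from a packaged 23-metabolite reference table
(multiplet positions, multiplicities, per-comparison effect directions and
fold changes), with log-normal concentration noise, residual water,
baseline, shift jitter and point noise. The generator's defaults are the
study conditions (38/32/40 samples per group).

## Worked example

```r
library(nmrmet)
library(dplyr)

ref <- metabolite_reference()                       # 23 serum metabolites
sp  <- simulate_cohort(ref, cohort_config(seed = 1)) # 110 spectra
b   <- sp |> reference_to_lactate() |> bin_spectra() |>
       exclude_water() |> normalize_total()
b
#> <nmr_binned> 110 samples x 9000 bins (500 masked), width 0.001 ppm, normalized

m <- fit_oplsda(filter_groups(b, c("polyp", "control")))
m
#> <nmr_latent> OPLSDA: 1 predictive component(s) + 1 orthogonal
#>   R2X = 0.212, R2Y = 0.939, Q2 = 0.838

q   <- quantify_metabolites(b, ref)
tab <- differential_table(q, list(polyp_vs_control = m), ref)
tab |> arrange(desc(vip)) |> head(3)
#>   metabolite comparison         vip     r class            fold_change direction
#> 1 Glutamate  polyp_vs_control  3.12  0.819 very_significant       1.36 up
#> 2 Lactate    polyp_vs_control  3.03  0.757 very_significant       1.45 up
#> 3 Aspartate  polyp_vs_control  3.00 -0.768 very_significant       1.26 down

feat <- ratio_feature(q, "Acetate", "Glycerol")
pc   <- feat[feat$group != "crc", ]
roc_curve(pc$ratio, droplevels(pc$group), positive = "polyp")
#> <nmr_roc> AUC = 0.951 (32 positive / 38 negative; positive class 'polyp')
#>   Youden cutoff = 2.361
```

Reading the output: the OPLS-DA cleanly separates polyp from control sera
(R²Y 0.94, Q² 0.84 — cross-validated, so not mere overfitting); glutamate
and lactate come out as the strongest differential metabolites with the
planted directions; and the acetate/glycerol ratio alone discriminates
polyps from controls with AUC 0.95 on this synthetic cohort. The critical
correlation thresholds for this comparison (n = 38 vs 32) are

```r
round(critical_r(38, 32, c(0.05, 0.01)), 3)
#> [1] 0.344 0.442
```

`run_pipeline(pipeline_config(seed = 1))` executes the whole workflow —
three pairwise OPLS-DA models with RPT and CV-ANOVA, the
differential-metabolite table, multivariate ROC and both ratio
diagnostics — and can write all artifacts (CSV/TSV/JSON plus a run
manifest) to a directory.

## Vignette

`vignettes/serum-nmr-workflow.Rmd` documents the models, the synthetic-data
generator and all numerical design choices.
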