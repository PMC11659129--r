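# dcekin

Quantitative pharmacokinetic analysis of dynamic contrast-enhanced (DCE)
MRI, built for studies that compare tracer-kinetic parameters between
malignant and normal tissue — the setting where a prostate lesion enhances
and washes out faster than healthy gland, and the question is which model
and which parameter separate the two classes best.

The package implements the full chain from raw dynamic signal to group
statistics:

- **Relaxometry.** Variable flip angle (VFA/DESPOT1) T1 and M0 estimation
  from the linearized spoiled gradient-echo (SPGR) equation, and
  frame-wise conversion of the dynamic signal to gadolinium concentration
  via the relaxation-rate difference
  `C(t) = (R1(t) − R1,pre) / r1`.
- **Arterial input function.** A documented parametric population AIF
  (gamma-variate first pass + exponential recirculation tail), extraction
  of a measured AIF from artery voxels (median over the mask, hematocrit
  correction `cp = cb / (1 − Hct)`), and bolus-arrival detection.
- **Six kinetic models**, all linear in the AIF, as forward
  (generative) implementations plus the derived-parameter algebra that
  expands them to the standard 30-parameter inventory:

  | model | free parameters | derived |
  |---|---|---|
  | Tofts | Ktrans, Ve | Kep = Ktrans/Ve |
  | extended Tofts (ETM) | Ktrans, Ve, Vp | Kep |
  | two-compartment exchange (`brix2c`) | F, PS, Vp, Ve | MTT = Vp/F, E = PS/(PS+F) |
  | adiabatic tissue homogeneity (ATH) | F, Tc, E, Ve | MTT = Tc, Vp = F·Tc, PS = −F·ln(1−E), Kep = E·F/Ve |
  | distributed parameter (DP) | F, Vp, Ve, PS | MTT = Vp/F, E = 1−e^(−PS/F) |
  | IAUC | IAUC60, IAUC90, IAUC60No, IAUC90No | — |

  Tissue curves are `Ct = F · (Ca ⊗ R)` with the model's impulse residue
  function `R(t)`; the DP model solves the plug-flow
  capillary/interstitium exchange system along flow characteristics in
  compiled code.
- **Voxel fitting.** Bounded Levenberg–Marquardt least squares with a
  deterministic multistart lattice of physiologically typical starting
  values, a machine-precision polish stage, and exclusion of voxels that
  fail to fit or return non-physiological values.
- **Cohort statistics.** ROI aggregation, two-sided Mann–Whitney U tests
  (exact where feasible), empirical ROC analysis with Youden-index
  cutoffs, and Spearman correlation matrices with the conventional
  strength categories.
- **Synthetic cohorts.** A generator that builds virtual subjects
  (dynamic + VFA series, masks, ground-truth parameter maps, AIF) around
  published lesion/normal median parameter values, so the entire pipeline
  is verifiable against known truth at desk scale.

Units follow the field's conventions: `F` and `PS` in mL/min/100 mL
tissue, `Ktrans`/`Kep` in 1/min, `Ve`/`Vp` in percent, `MTT`/`Tc` in
seconds, concentrations in mM.

## Worked example

Simulate 60 lesion and 60 normal ROIs around the published tissue
medians (log-normal dispersion 0.5, 1% signal noise), push them through
the full signal chain, fit the Tofts model per ROI, and ask how well the
fitted transfer constant separates the classes:

```r
library(dcekin)

sim <- simulate_roi_curves(n_lesion = 60, n_normal = 60, model = "tofts",
                           dispersion = 0.5, noise_frac = 0.01, seed = 42)
fit <- fit_kinetic(sim$curves, sim$aif, model = "tofts")
glance(fit)
#> # A tibble: 1 × 6
#>   model n_curves n_converged n_valid n_excluded median_rss
#>   <chr>    <int>       <int>   <int>      <int>      <dbl>
#> 1 tofts      120         120     120          0   0.000545

res <- fit$results
roc_analysis(res$Ktrans[res$tissue_class == "lesion" & res$valid],
             res$Ktrans[res$tissue_class == "normal" & res$valid])
#> # A tibble: 1 × 6
#>     auc cutoff sensitivity specificity accuracy direction
#>   <dbl>  <dbl>       <dbl>       <dbl>    <dbl> <chr>
#> 1 0.965 0.0977        0.85           1    0.925 >=
```

All 120 noisy ROI fits converge and pass the physiological filter; the
empirical ROC says a Ktrans cutoff of about 0.1/min classifies lesion vs
normal with AUC 0.96 on this synthetic cohort — lesion Ktrans (median
0.15/min) sits well above normal tissue (0.04/min), so the transfer
constant is an effective discriminator here by the usual AUC > 0.8 rule.

`autoplot(fit)` overlays fitted model curves on the simulated data;
`build_report()` assembles the per-parameter median/U-test table, the ROC
table, and the DP×ETM Spearman matrix for a full multi-model cohort run
(see `run_pipeline()` for the end-to-end volumetric version, from NIfTI
volumes to report CSVs).

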