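---
title: "Tracer-kinetic models for DCE-MRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracer-kinetic models for DCE-MRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcekin)
```

## The problem

Dynamic contrast-enhanced (DCE) MRI acquires rapid serial T1-weighted
images while a gadolinium bolus transits the tissue. Malignant prostate
tissue is more vascular and more permeable than normal gland, so its
concentration-time curve rises faster and washes out earlier. Fitting a
tracer-kinetic model voxel by voxel converts those curves into
physiological parameters — flow, permeability, compartment volumes — and
the clinical question becomes statistical: which parameter, from which
model, best separates lesions from normal tissue?

`dcekin` implements that whole chain: signal → concentration →
voxel-wise model fits → ROI aggregation → group statistics, plus a
synthetic-cohort generator with known ground truth so each stage can be
validated quantitatively.

## Signal model and relaxometry

All signal synthesis and inversion goes through the spoiled
gradient-echo (SPGR) steady-state equation

$$S = M_0 \sin\alpha \, \frac{1 - E_1}{1 - E_1\cos\alpha},
  \qquad E_1 = e^{-TR \cdot R_1},$$

with $R_1(t) = 1/T_{10} + r_1 C(t)$. The default protocol mirrors a fast
3D prostate acquisition: TR = 2.8 ms, dynamic flip 15°, pre-contrast
variable flip angles (VFA) 5°/10°/15°, 120 dynamic frames at 2 s.

*T1 mapping.* The VFA fit is the standard linearization: regressing
$S/\sin\alpha$ on $S/\tan\alpha$ gives slope $E_1$, hence
$T_1 = -TR/\ln E_1$, and $M_0$ from the intercept. Slopes outside
$(0,1)$ or degenerate regressions (all-zero signals) are flagged invalid
rather than propagated. The linearized estimator is exactly the
least-squares solution at zero noise; under noise it differs from the
nonlinear maximum-likelihood fit draw by draw, which is why the tests
compare the two estimators on medians, not per draw.

*Concentration.* Each dynamic frame is inverted analytically:
$B = S/(M_0\sin\alpha)$, $E_1 = (1-B)/(1-B\cos\alpha)$,
$R_1 = -\ln E_1/TR$. The pre-contrast reference $R_{1,\text{pre}}$ is
the mean over the first `n_baseline` dynamic frames (default 5) rather
than $1/T_1$ from the VFA fit alone; both values are reported and their
discrepancy is available as an attribute, since vendor pipelines differ
on this point. Frames at or beyond the SPGR saturation value
$M_0\sin\alpha$ have no inverse; they are flagged and set to `NA`, never
clipped, and a voxel is excluded when more than 10% of its frames are
non-invertible (the threshold is ours; it mirrors the usual exclusion of
failed voxels).

Relaxivity defaults to $r_1 = 3.7\,$/mM/s, a gadopentetate value at 3 T.
Native T1 defaults are 1.4 s for prostate tissue and 1.7 s for blood;
both are configurable, as no single pair fits every scanner and field
strength.

## The six kinetic models

All tissue models are linear, time-invariant systems driven by the
plasma concentration $C_a(t)$: $C_t = F_p\,(C_a \otimes R)$ with an
impulse residue function $R(t)$, $R(0)=1$. Unit conventions: $F$ and
$PS$ in mL/min/100 mL tissue, $K^{trans}$ in 1/min, $V_e, V_p$ in
percent, transit times in seconds. Internally everything is converted to
1/s and volume fractions.

- **Tofts**: $R(t) = e^{-K_{ep}t}$ scaled by $K^{trans}$, with
  $K_{ep} = K^{trans}/V_e$. No vascular term.
- **Extended Tofts (ETM)**: adds $V_p C_a$.
- **Two-compartment exchange** (`brix2c`, the conventional
  two-compartment model): well-mixed plasma and interstitial pools,
  $$V_p \dot C_1 = F(C_a - C_1) + PS(C_2 - C_1), \qquad
    V_e \dot C_2 = PS(C_1 - C_2),$$
  solved through its bi-exponential impulse response (eigendecomposition
  of the 2×2 system). When the eigenvalues coincide the code switches to
  the repeated-root closed form $(a + bt)e^{\lambda t}$ convolved
  numerically.
- **Adiabatic tissue homogeneity (ATH)**: plug-flow capillary of transit
  time $T_c$, then adiabatic exchange:
  $R(t) = 1$ for $t < T_c$, $R(t) = E\,e^{-(EF/V_e)(t - T_c)}$ after.
- **Distributed parameter (DP)**: the axially distributed exact
  counterpart of ATH — a plug-flow capillary exchanging locally with a
  stationary interstitium along its length,
  $$v_p \partial_t C_c + FL\,\partial_x C_c = -PS(C_c - C_e), \qquad
    v_e \partial_t C_e = PS(C_c - C_e),$$
  inlet $C_c(0,t) = C_a(t)$, with $T_c = V_p/F$.
- **IAUC**: trapezoidal area under the concentration curve over 60 s and
  90 s from bolus arrival, optionally normalized by the same integral of
  the arterial curve.

### Derived parameters and conventions

Each model's free parameters are expanded to the standard reported
inventory (6 DP + 3 Tofts + 4 ETM + 6 two-compartment + 7 ATH + 4 IAUC
= 30 quantities). Three conventions required a decision, because
published median tables are the only constraint available:

- **Flow/permeability units.** $F$ and $PS$ are interpreted as
  mL/min/100 mL even where tables print mL/min/mL: only the per-100-mL
  reading makes the printed magnitudes internally consistent (e.g. DP
  lesion $T_c = V_p/F \approx 6.5$ s against a printed MTT of 5.28 s,
  versus 0.065 s under the literal reading).
- **MTT convention.** MTT is the *vascular* transit $V_p/F$ for DP and
  the two-compartment model, and $T_c$ for ATH. The alternative
  $(V_p+V_e)/F$ (total distribution volume over flow) produces values an
  order of magnitude larger than published ones.
- **Extraction convention.** $E = PS/(PS+F)$ for the well-mixed
  two-compartment model and $E = 1 - e^{-PS/F}$ for the plug-flow
  models. Both reproduce the corresponding published median relations to
  within a few percent when evaluated at the published free-parameter
  medians — the residual discrepancy is expected, since voxel-wise
  medians of derived quantities need not equal derived quantities of
  medians.

### Numerics

Concentration curves are treated as piecewise linear in time.
Exponential convolutions use the analytically exact recursion for
piecewise-linear inputs (stable `expm1` forms, series fallback for
$k\,\Delta t < 10^{-6}$), so Tofts/ETM/two-compartment forwards are
exact up to AIF interpolation error, $O(\Delta t^2)$ on smooth inputs.
The ATH boxcar term integrates the piecewise-linear AIF exactly across
the $T_c$ breakpoint, so sub-frame transit times (the normal-tissue
regime, $T_c \approx 0.2$–1.3 s against 2 s frames) produce no grid
artifacts.

The DP model is solved along flow characteristics: the capillary is
split into `n_seg` segments (default 50, refusal below 8), each time
step of $h = T_c/n_{seg}$ advances parcels one segment while the local
two-pool exchange is integrated exactly (the difference $C_c - C_e$
decays at $PS/v_p + PS/v_e$; their weighted sum is conserved). The
entering parcel carries the trapezoidal average of the inlet over the
step, which keeps the pure plug-flow limit second-order accurate. When
$T_c$ falls so far below the frame spacing that the internal grid would
explode, the step is re-based on the frame grid and the segment count
adapts — the capillary phase is unresolved by the data in that regime,
so nothing is lost. Doubling `n_seg` from 50 changes the default test
curves by under 0.05%, and the solver agrees with an independent
numeric inverse-Laplace oracle of the same system to a few parts in
$10^5$; an operator choosing `n_seg` is trading runtime against error
far below measurement noise.

## Voxel fitting

Fits minimize the unweighted sum of squared concentration residuals
under box bounds (Levenberg–Marquardt, `minpack.lm`), from a fixed
deterministic lattice of starting values capped at 27 starts. The start
levels are physiologically typical soft-tissue values (e.g. Ktrans
0.03/0.15/0.7 per minute; flows 8–45 mL/min/100 mL), not bound-derived
extremes: perfusion objectives are multi-modal along ridges, and a start
within a factor of a few of the truth reliably lands in the right basin.
The best start by residual then receives a machine-precision polish
(`ftol = ptol = 1e-15`, up to 4 rounds): on nearly flat ridges the
standard stopping rule halts visibly short of the minimum while the
exact minimum is still reachable, and the polish walks the remaining
distance.

The flat-ridge case is not hypothetical. For ATH at normal-tissue
parameters ($T_c \approx 0.23$ s, far below the 2 s frame spacing), only
the products $E \cdot F$, $F \cdot T_c$ and the rate $EF/V_e$ shape the
curve; curves along the ridge differ by parts in $10^6$. With exact
(noise-free) data the polish recovers the true parameters to machine
precision, but with measurement noise the individual factors $F$, $T_c$,
$E$ are effectively unidentifiable at this temporal resolution — users
should interpret ATH parameters in normal tissue through the identifiable
combinations. The same caution applies, more mildly, to DP's $V_p$ at
small transit times.

A fitted voxel is *valid* when the optimizer converged and the full
(free + derived) parameter set passes the physiological filter:
$V_e, V_p \in [0, 100]\%$ with $V_e + V_p \le 100$, $E < 100\%$,
$F \le 300$ mL/min/100 mL, $K^{trans} \le 5$/min, MTT $\le 120$ s (all
configurable; published pipelines exclude "non-physiological" voxels
without printing their thresholds, so these are declared defaults).
Exclusion reasons are accounted per voxel: `fit_failure`,
`non_physiological`, or `non_invertible_frames`.

No per-voxel bolus-arrival delay is fitted: tissue and AIF share the
acquisition clock, which is exactly true for the synthetic cohort and an
approximation for real data.

## Arterial input function

The measured-AIF path takes the voxel-wise *median* over the artery mask
per frame (robust to partial-volume outliers) and converts whole blood
to plasma via $c_p = c_b/(1 - \text{Hct})$ with Hct = 0.42 by default;
setting Hct = 0 reproduces a no-correction analysis, since published
pipelines do not always state whether the correction was applied.

The population AIF is a gamma-variate first pass plus an exponential
recirculation tail,

$$c_p(u) = a_1 u^{\alpha} e^{-u/\beta} +
  a_2 (1 - e^{-u/\tau_r}) e^{-u/\tau_d},$$

with documented default coefficients giving a ~6 mM peak about 10 s
after bolus arrival. It is a stand-in shape for synthesis and testing,
not a fitted population model.

Bolus arrival is the first frame exceeding baseline mean + 3 SD that
does not decrease over the next two frames, with a global-max
backtracking fallback for noise-free ramps whose baseline SD is zero.

## The synthetic cohort: what it does and does not emulate

`generate_subject()` and `simulate_roi_curves()` build virtual data
around published lesion/normal median parameter values
(`reference_medians()`): each free parameter is drawn log-normally with
the published median and log-scale dispersion 0.5 by default. Published
tables report only medians; the log-normal choice supplies positivity
and the heavy right tail typical of perfusion parameters, and dispersion
0.5 gives between-ROI spread comparable to the published lesion/normal
contrasts. Draws violating the physiological bounds are rejected and
redrawn, so generator and exclusion rules agree by construction. Noise
is additive zero-mean Gaussian on the magnitude signal (default SD 1% of
the baseline tissue signal) — adequate at this SNR, though not Rician;
the generator takes the noise level as a plain parameter, so a Rician
variant is a one-line change at the call site.

The cohort is deliberately minimal in every other respect: voxels are
assigned to tissue classes by index (no anatomical geometry), all tissue
voxels share one native T1, there is no motion, no $B_1$ error, no
partial-volume mixing, and ROIs are index blocks of configurable size.
Passing tests on this cohort therefore demonstrates the *correctness of
the computational chain* — inversion, fitting, statistics — under the
stated noise model, not robustness to the artifacts of real prostate
imaging (registration error being the dominant one at 2 s sampling).

## Statistics

- **Mann–Whitney U**, two-sided, with $U$ counted as
  $\#\{x_i > y_j\} + \tfrac12\#\{\text{ties}\}$. The p-value is exact
  through the Wilcoxon null distribution for tie-free samples with
  $n_x n_y \le 400$, exact by full enumeration of group assignments for
  tied samples when $\binom{n_x+n_y}{n_x} \le 2\times10^5$, and
  otherwise the normal approximation with tie correction and continuity
  correction. (Full enumeration at the largest tie-free sizes the exact
  rule covers, e.g. 20 + 20, would cost $\sim 10^{11}$ evaluations; the
  distribution-based path is exact there at no cost.)
- **ROC** over all observed thresholds; AUC by the rank (Mann–Whitney)
  formulation, which equals the trapezoid under the empirical curve with
  ties counted half. Orientation is fixed per parameter so AUC ≥ 0.5,
  and the direction is reported — some parameters (e.g. the
  two-compartment model's $V_e$) run higher in normal tissue. The cutoff
  maximizes Youden's $J$; ties break toward higher specificity. The
  AUC > 0.8 threshold used in reports is the conventional
  "effective discriminator" rule.
- **Spearman** rho with average ranks (p from the t approximation),
  categorized as strong ($0.8 < |r| \le 1$), moderate
  ($0.5 < |r| \le 0.8$), weak ($0.3 < |r| \le 0.5$), none
  ($|r| \le 0.3$) — half-open intervals applied exactly.
- **ROI aggregation** by median over valid voxels (mean selectable);
  an ROI is dropped when fewer than 25% of its voxels are valid.
  No multiple-testing correction is applied, and ROIs are treated as
  independent observations — both choices replicate the published
  analysis design rather than endorse it; with hundreds of ROIs from
  tens of subjects, within-subject clustering would otherwise call for a
  mixed model.

## Problem sizes and determinism

The shipped tests validate forward models on the 120-frame default grid;
parameter recovery at both lesion and normal medians for all five
fittable models; noisy recovery on 500 simulated ROIs (Tofts); the ROC
acceptance cohort at 200 + 200 ROIs; and the volumetric pipeline
end-to-end on small grids (tens of voxels, all six models). These sizes
keep the full suite at a few minutes on one CPU while exercising every
code path; nothing in the methods limits larger volumes beyond linear
runtime. Every stochastic step is seeded: subjects are bit-identical
under a fixed seed, and volume fitting contains no randomness at all, so
pipeline reruns hash identically.

## Known limitations

- No image registration, $B_1$/flip-angle-error correction, or
  water-exchange modeling; concentration linearity in $1/T_1$ is assumed
  throughout.
- The AIF is taken as delay- and dispersion-free relative to the tissue.
- ATH (and to a lesser degree DP) parameters are ridge-unidentifiable at
  sub-frame transit times, as discussed above.
- The synthetic cohort validates computation, not anatomy; claims about
  real-world discriminative performance must come from real cohorts.
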