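---
title: "Population pharmacokinetics and limited sampling strategies for treosulfan: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics and limited sampling strategies for treosulfan: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Treosulfan is an alkylating prodrug used in myeloablative conditioning
before hematopoietic stem cell transplantation.  Exposure is summarised by
the area under the plasma concentration-time curve from the start of the
infusion to infinity (AUC~0→∞~).  Measuring it directly needs a full
concentration-time profile — ten blood draws in a child who is about to
undergo transplantation.  A *limited sampling strategy* (LSS) replaces the
full profile with two or three well-chosen samples plus an estimator, either
a multiple-regression equation or Bayesian estimation of the individual's
pharmacokinetic parameters under a fixed population model.

`treopk` implements the whole chain: the population model, a virtual-cohort
simulator, non-compartmental reference AUC, LSS search and validation,
Bayesian individual estimation, the Sheiner–Beal error metrics, and a
nonlinear mixed-effects (NLME) fitting engine with the associated
diagnostics (likelihood-ratio model comparison, η-shrinkage, bootstrap,
prediction-corrected visual predictive check).

## The population model

Disposition follows a linear two-compartment model with zero-order infusion
input.  For subject $i$ and parameter $j \in \{Cl, V_1, Q, V_2\}$:

$$\theta_{ij} = \theta_j \left(\frac{BW_i}{70}\right)^{\beta_j} e^{\eta_{ij}},
\qquad \eta_i \sim N(0, \Omega)$$

with allometric exponents fixed at $\beta = 0.75$ for clearance and $1$ for
the volumes.  Two deliberate structural asymmetries reflect the final model:
intercompartmental clearance $Q$ carries interindividual variability (IIV)
but no bodyweight covariate (adding it worsened the fit of the original
analysis), and the peripheral volume $V_2$ is weight-scaled but carries no
IIV (its variability was not estimable).  $\Omega$ covers
$(\eta_{Cl}, \eta_{V_1}, \eta_Q)$ with one free correlation, between
$\eta_{Cl}$ and $\eta_{V_1}$.  The reported ω~Cl-V1~ of 71.4% is interpreted
as that correlation coefficient (0.714), the usual reporting convention of
the estimation software used for the original analysis.

Observations follow a proportional residual-error model
$C_{obs} = C_{pred}(1 + \varepsilon_1)$, $\varepsilon_1 \sim N(0, b^2)$ with
$b = 0.188$; the additive component of the general combined model is zero in
the final model.  Negative simulated concentrations are truncated at zero
and counted — at $b = 0.188$ this is a sub-0.01% event with negligible bias.

The packaged configuration (`final_model()`) carries the published typical
values referenced to 70 kg: Cl 14.7 L/h, V~1~ 26.0 L, Q 2.25 L/h, V~2~
9.93 L; IIV SDs 0.255/0.514/0.386; correlation 0.714; b 0.188.

The concentration function is the closed-form bi-exponential infusion
solution with micro constants $k_{10} = Cl/V_1$, $k_{12} = Q/V_1$,
$k_{21} = Q/V_2$ and disposition exponents from the characteristic
quadratic; it is continuous at the end of infusion and degenerates cleanly
to the one-compartment form at $Q = 0$.  The tests verify it against an
independent ODE integration to a relative tolerance of 10^-6^ and verify
that its time integral equals $D/Cl$.

**Units.**  Concentration mg/L, time h, dose mg throughout.  The source
analyses mixed µM and ng/mL; the mg-based system keeps $AUC = D/Cl$
dimensionally clean, and all relative metrics (R², MPE/MAPE/RMSE) are unit
invariant.  Because both AUC (mg·h/L) and concentration (mg/L) are mg-based,
the regression coefficients are directly comparable to the published
equations.

## The virtual cohort

`simulate_group()` generates one dosing group: bodyweights from a normal
distribution with mean 26.9 kg and SD 15.7 kg truncated to [5, 55] kg (the
study population's summary; the bounds bracket its realized 7.7–52 kg
range), body surface area from the weight-only formula
$BSA[\mathrm{cm^2}] = 4.688\, BW[\mathrm{g}]^{0.8168 - 0.0154 \log_{10} BW}$,
total dose as dose level (g/m²) × BSA, random effects from $\Omega$, and
profiles over the candidate grid 0.5, 1, 1.5, 2, 2.5, 3, 4, 6, 8, 12 h after
infusion start.  Records below the limit of quantification (default
0.0556 mg/L ≡ 0.2 µM) are flagged and excluded from analysis, never imputed.
The LOQ is configurable because the source reports two inconsistent values
(0.56 and 56.6 ng/mL); at either value no on-grid sample at or before 8 h is
censored, so LSS results are insensitive to the choice.

**Residual noise in the LSS workflow.**  `simulate_group()` applies the
proportional error model by default.  The LSS development workflow
(`lss_develop()`), however, simulates *noise-free* profiles (IIV only).
This is a substantive design decision: the published simulation study's
performance surface (adjusted R² of 0.974–0.9998, regression MAPE of
0.45–2.78%) is only attainable when the virtual samples carry no assay
noise — with 18.8% proportional noise on every sample the best two-point
regressions cannot exceed R² ≈ 0.9 and MAPE ≈ 8–10% — and the original
removal rule for censored samples is phrased in terms of *predicted*
concentrations.  Bayesian MAP estimation still assumes $b = 0.188$ in its
objective, because the population estimates are fixed wholesale during
individual estimation.  Consequently the reported LSS performance
characterises *model-intrinsic* prediction error (how much information two
or three sampling times carry about AUC under interindividual variability),
not assay reproducibility; a real deployment adds assay noise on top.

## Non-compartmental reference AUC

The "observed" AUC that every strategy is scored against is
non-compartmental: linear-up/log-down interpolation between quantifiable
records anchored at (0, 0) — the dose is an infusion starting at $t = 0$ —
plus log-linear terminal extrapolation $C_{last}/\lambda_z$.  The terminal
window is chosen by best adjusted R² over tail windows of at least three
points that never include the peak, the common automatic rule in NCA
software.  On noise-free profiles over the candidate grid this pipeline is
within 2% of $D/Cl$ (verified across parameter sweeps), and because the same
reference is used for learning and validation, the small discretization bias
cancels from the prediction-error metrics.

## LSS development

Admissible sampling sets are all 2- or 3-subsets of the candidate grid with
every time at or after the end of infusion and excluding 12 h.  "At or
after" is deliberate: drawing *during* the infusion is excluded, but the
end-of-infusion time itself is allowed — the published 2-h-infusion
equations use the 2-h sample.  Each group of 100 virtual patients is split
50:50 into learning and validation halves at the subject level (the split
seed is explicit; the original split seed is unknown).  Ordinary least
squares of the NCA AUC on the concentrations at each candidate set is ranked
by adjusted R² with a deterministic tie-break (earliest times, then fewer
samples).  The winning sets are validated on the held-out half; Bayesian MAP
estimation restricted to the same times is scored on the full group.

`estimate_individual()` minimises the standard MAP objective — proportional
Gaussian data term plus $\eta^T \Omega^{-1} \eta$ — by quasi-Newton descent
from the zero start plus five prior-drawn starts.  The posterior-mode
default was chosen over the conditional mean for speed and determinism;
`conditional_mean_estimate()` provides the Metropolis-within-Gibbs
conditional mean as an alternative and the two agree closely in this
near-Gaussian setting (verified in the tests).

## NLME estimation

`fit_population()` maximises the marginal likelihood with the subject-level
random effects integrated out by the Laplace approximation: an inner damped
Newton solver (finite-difference derivatives, warm-started across outer
iterations, with a quasi-Newton polish whenever Newton stalls) finds each
subject's MAP $\eta$, and an outer BFGS run with an explicit
central-difference gradient optimises the transformed population parameters
(log scale for positive parameters, Fisher-z for the correlation).  One
outer restart guards against stalls on the flat variance directions.  The
final objective value (MOFV, $-2\log L$) is recomputed by importance
sampling with the Laplace Gaussian as proposal — the method the original
analysis used for final model selection — with its Monte-Carlo standard
error attached.  Direct maximisation was chosen over a stochastic EM scheme
because every problem in scope (≤ 100 subjects, ≤ 10 observations each) is
comfortably within the Laplace regime; the approximation can bias variance
components by a few percent, which is visible in the tests' looser
tolerances for ω and the correlation but does not affect the structural
parameters or the residual error at the tested scales.

Standard errors come from the numerically differentiated observed
information on the transformed scale, delta-transformed back.  Model
comparison applies the MOFV decision rules of the original analysis: a drop
of more than 10.8 for structural/forward inclusion (χ²~1~ at p < 0.001) and
6.67 for backward retention (p < 0.01), alongside AIC/BIC.  η-shrinkage is
$1 - \mathrm{Var}(\hat\eta)/\hat\omega^2$ per random effect.  The bootstrap
resamples subjects with replacement and refits; the pcVPC
prediction-corrects observations and simulations by the bin-median typical
prediction before comparing 5th/50th/95th percentiles, with per-time bins by
default (sparse bins merged with a neighbour).

A one-compartment structure (IIV on Cl and V~1~ with correlation) and a
three-compartment structure (second peripheral compartment without IIV,
solved by eigendecomposition) are provided for the structural-selection
harness; the tests reproduce the original selection outcome — the
two-compartment model beats the one-compartment model by far more than the
10.8 threshold on two-compartment data.

## Problem sizes and reproducibility

All simulation-based checks use the study's own scales: 100 virtual patients
per dosing group for LSS development, 100 subjects on the full candidate
grid for the NLME recovery and structural-selection checks; smaller cohorts
(8–50 subjects) exercise the bootstrap and pcVPC mechanics, with the
bootstrap's replicate count reduced to single digits in tests since only the
resample-refit-summarise mechanics are under test there.  Every stochastic
operation takes an explicit seed; `child_seed()` expands one master seed
into decorrelated per-stage streams, so every dataset, split, Monte-Carlo
run and importance-sampling evaluation is exactly reproducible from a single
integer.

## Known limitations

* The selection of the *best* sampling set is a near-tie decision among the
  top candidates (adjusted R² differences of a few 10^-3^).  For the 2-h
  infusion groups the search reproduces the published winning sets almost
  deterministically; for the 1-h infusion group it consistently prefers
  {1, 4} h (2-point) and {1, 2.5, 8} h (3-point) over the published
  {1.5, 6} / {1, 2, 6} even in the large-n limit, while reproducing the
  published sets' *performance* within tolerance.  The published account of
  that group is itself ambiguous (its abstract and its results table give
  different 2-point sets), so the package treats the performance surface,
  not the identity of the near-tied winner, as the reproducible quantity.
* Metabolite (epoxide) kinetics are out of scope; the model describes the
  prodrug only.
* The Laplace-based engine is not a reimplementation of any specific
  commercial estimator; MOFV values are comparable within this package, not
  across software.
* The virtual cohort emulates the covariate distribution, dosing groups and
  sampling designs of one pediatric study; passing tests demonstrate
  internal consistency under those conditions, not predictive performance in
  other populations (different weight ranges, renal function, or assay
  error).
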