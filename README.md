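# treopk

Population pharmacokinetics of treosulfan and limited sampling strategies
for estimating exposure in children before hematopoietic stem cell
transplantation.

Treosulfan is an alkylating prodrug given as a 1-h or 2-h intravenous
infusion at 10–14 g/m². Exposure is the area under the concentration–time
curve, AUC₀→∞ = D/Cl for this linear drug. Measuring it needs a full
10-sample profile; a **limited sampling strategy (LSS)** predicts it from
two or three samples, either through a regression equation

AUC_pred = a₀ + Σₖ aₖ·C(tₖ)

or through Bayesian (MAP) estimation of the individual parameters under a
fixed population model. The package implements the full pipeline around a
two-compartment population model with allometric bodyweight scaling

θᵢⱼ = θⱼ · (BWᵢ/70)^βⱼ · e^ηᵢⱼ,  η ~ N(0, Ω),  C_obs = C_pred·(1 + ε₁)

with β = 0.75 for clearance, 1 for volumes, correlated η_Cl/η_V1, and
proportional residual error (b = 0.188):

* analytic two-compartment infusion model and virtual pediatric cohorts
  (`concentration()`, `simulate_group()`, `final_model()`);
* non-compartmental AUC₀→∞ by linear-up/log-down with terminal
  extrapolation (`nca_auc_inf()`, `nca_dataset()`);
* exhaustive LSS search, validation and Bayesian MAP estimation
  (`lss_develop()`, `rank_strategies()`, `estimate_individual()`);
* Sheiner–Beal prediction-error metrics (`lss_performance()`);
* NLME fitting by Laplace-approximated marginal likelihood with
  importance-sampled MOFV, LRT model comparison, η-shrinkage, bootstrap and
  prediction-corrected VPC (`fit_population()`, `compare_models()`,
  `bootstrap_population()`, `pcvpc()`).

## Worked example

Develop and validate 2- and 3-point strategies on 100 virtual patients per
dosing group:

```r
library(treopk)
dev <- lss_develop(final_model(), n = 100, seed = 1)
dev
#> LSS development (100 subjects/group, seed 1):
#>     group k       mode   times adj_r2      mpe   mape   rmse
#> 1  12g-1h 2 regression     1,3 0.9716  0.27605 2.4702 3.1988
#> 2  12g-1h 2   bayesian     1,3     NA -1.96324 5.5166 6.9768
#> 3  12g-1h 3 regression 1,2.5,8 0.9996 -0.02214 0.2712 0.3464
#> 4  12g-1h 3   bayesian 1,2.5,8     NA -2.44123 3.8665 4.6699
#> 5  12g-2h 2 regression     2,6 0.9970 -0.81585 1.7671 2.2534
#> 6  12g-2h 2   bayesian     2,6     NA -3.22024 5.2679 6.6076
#> 7  12g-2h 3 regression   2,4,8 0.9997 -0.39997 0.7005 0.9902
#> 8  12g-2h 3   bayesian   2,4,8     NA -3.42145 4.9655 6.2918
#> 9  14g-2h 2 regression     2,6 0.9918  0.37200 1.2558 1.5347
#> 10 14g-2h 3 regression   2,4,8 0.9990  0.16587 0.3886 0.4757
#> ...
```

Each row is one strategy: the sampling times (h after infusion start), the
learning-set adjusted R² of the regression equation, and the validation-set
mean (MPE), mean-absolute (MAPE) and root-mean-square (RMSE) relative
prediction errors in percent. For the 12 g/m² 2-h infusion group, samples
at 2 h and 6 h predict AUC₀→∞ with a 1.8% mean absolute error; Bayesian
estimation from the same two samples is less precise (MAPE ≈ 5%) but needs
no fitted equation. The winning equation itself:

```r
dev$models[["12g-2h/2pt/regression"]]
#> LSS (regression): AUCpred = 1.99*C_2h + 7.55*C_6h +75.5  [adj R2 = 0.9970]
```

Predict a new patient's exposure from two measured concentrations
(mg/L) and score predictions:

```r
predict_auc(dev$models[["12g-2h/2pt/regression"]], c(350, 45))
#> [1] 1110.664
lss_performance(c(110, 90), c(100, 100))
#> Prediction performance (n = 2): MPE 0.00%, MAPE 10.00%, RMSE 10.00%; PE > +20%: 0, PE < -20%: 0
```

Fit the population model to a simulated rich-sampling cohort and test the
structural model:

```r
ds   <- simulate_group(final_model(), 12, 2, n = 100, seed = 11)
fit2 <- fit_population(ds, n_compartments = 2, seed = 1)
fit1 <- fit_population(ds, n_compartments = 1, seed = 1)
fit2
#> Population fit (2-compartment, 100 subjects, 1000 obs): MOFV 10116.10, AIC 10134.10, BIC 10157.55
#> Population PK model (ref 70 kg):
#>   Cl 14.5 L/h (beta 0.75, omega 0.235)
#>   V1 26.39 L   (beta 1, omega 0.436)
#>   Q  2.473 L/h (beta 0, omega 0.284)
#>   V2 10.01 L   (beta 1, no IIV)
#>   corr(eta_Cl, eta_V1) 0.563; proportional error 0.197; additive 0 mg/L
#> eta-shrinkage [%]: cl 5.1, v1 8.3, q 62.7
compare_models(fit1, fit2)$delta_mofv
#> [1] 795.1069
```

The estimates recover the generating model (Cl 14.7 L/h, V1 26.0 L, Q
2.25 L/h, V2 9.93 L, b 0.188), and the two-compartment model beats the
one-compartment alternative by a MOFV drop of ~795, far beyond the 10.8
(p < 0.001) decision threshold.

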