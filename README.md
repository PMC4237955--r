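# bayeslss

Bayesian limited sampling strategies (B-LSS) for estimating the cyclosporine
area under the concentration-time curve (AUC<sub>0–12</sub>) in pediatric
hematopoietic stem cell transplantation.

Cyclosporine has a narrow therapeutic window and large pharmacokinetic
variability, and AUC-guided dose adjustment needs the full 12-hour exposure —
but eight or nine blood draws per interval are not realistic in children. A
B-LSS predicts the full-interval AUC from one to four samples drawn within a
few hours of the dose: a population pharmacokinetic model acts as the
Bayesian prior, the few measured concentrations update the subject's random
effects by empirical Bayes (MAP) estimation, the individual curve is
reconstructed on the full nine-point sampling grid, and its trapezoidal AUC
is the prediction. The package is aimed at pharmacometricians and
methodologists who want to develop, validate or stress-test such strategies
in simulation.

## What is inside

- **PK engine** — analytic one-/two-compartment steady-state concentrations
  with zero-order infusion, first-order absorption, lag time and
  bioavailability; linear trapezoidal AUC
  (`structural_params()`, `steady_state_concentration()`,
  `trapezoidal_auc()`).
- **Population model** — exponential inter-individual variability
  θ<sub>i</sub> = θ·exp(η<sub>i</sub>) on CL, Q, KA, F with a slope-linked Vc
  effect and CL–Q correlation; allometric weight scaling
  (WT/35)<sup>3/4</sup> on clearances, (WT/35)<sup>1</sup> on volumes;
  multiplicative covariate terms; combined residual error
  C<sub>obs</sub> = C<sub>pred</sub>(1 + ε₁) + ε₂
  (`population_model()`, `typical_params()`, `residual_variance()`). The
  published structural and final covariate models for pediatric HSCT are
  built in (`csa_structural_model()`, `csa_final_model()`).
- **Cohort simulator** — virtual pediatric cohorts with the study's
  structure: steady-state BID profiles on the nominal 9-point grids,
  covariates in the published ranges, 30/1500 ng/mL assay limits, and a
  ground-truth sidecar that replays every observation exactly
  (`cohort_spec()`, `generate_dataset()`).
- **Estimation** — MAP individual estimation (penalised weighted least
  squares with the log-variance term, Gauss-Newton with safeguards) and
  population fitting by Laplace-approximated marginal likelihood with a
  FOCE-like Hessian; likelihood-ratio model comparison and stepwise
  covariate search (`map_estimate()`, `fit_population()`, `lrt_compare()`,
  `covariate_search()`).
- **LSS engine** — exhaustive enumeration of all 255 designs of 1–4 points,
  leave-one-out cross-validated AUC prediction with per-fold refits, error
  indices (ME%, RMSE%, 95th PAE%, error categories, bootstrap CIs), observed
  vs *underlying* (residual-error-free) AUC targets, and representative
  shortlists under the clinical constraints (pre-dose sample included,
  ≤ 4 h window) (`enumerate_lss()`, `loocv_evaluate()`, `error_indices()`,
  `select_representatives()`, `underlying_auc()`).
- **Pipeline** — a YAML-configurable driver that simulates, fits model
  variants, sweeps designs and writes publication-shaped CSVs with a full
  reproducibility manifest (`run_config()`, `run_pipeline()`), plus a thin
  CLI (`inst/cli/bayeslss.R`).

## Worked example

Simulate a 10-profile IV cohort from the published structural model, refit
it, and evaluate three candidate designs by cross-validation:

```r
library(bayeslss)

model  <- csa_structural_model("combined")   # two-compartment, 17.5% + 15 ng/mL error
spec   <- cohort_spec(n_iv_profiles = 10, n_po_profiles = 0, seed = 2024)
cohort <- generate_dataset(spec, model = model)

fit <- fit_population(cohort, model, control = list(restarts = 1))
print(fit)
#> Population fit: 10 subjects, 90 observations, OFV 951.479
#>   theta: CL=16.24 Vc=37.56 Q=13.42 Vp=108.6 KA=0.71 ALAG=0.39 F=0.61
#>   IIV sd: CL=0.196 Q=0.749 KA=0.83 F=0.32
#>   error: add 15.41 prop 0.1784 | convergence code 0

designs <- list(lss_design(c(0, 2, 3, 4)),   # pre-dose + 2, 3, 4 h
                lss_design(c(2, 2.5, 8)),
                lss_design(0))               # trough only
evals <- loocv_evaluate(cohort, model, designs, refit = FALSE, fitted = fit)
for (e in evals) print(e)
#> LSS C0, C2, C3, C4 [observed AUC, N=10]: 95th PAE% 17.79 | RMSE% 9.48 (4.65, 13.19) | ME% 0.02 (-5.28, 5.78)
#> LSS C2, C2.5, C8 [observed AUC, N=10]: 95th PAE% 15.97 | RMSE% 9.80 (6.66, 12.53) | ME% -2.05 (-7.80, 3.85)
#> LSS C0 [observed AUC, N=10]: 95th PAE% 36.61 | RMSE% 21.05 (13.28, 27.23) | ME% 1.75 (-10.59, 14.33)
```

Read: the practical four-point design (pre-dose plus 2, 3, 4 h) predicts the
observed AUC with a 95th percentile of absolute relative errors of ~18% and
no systematic bias (ME% ≈ 0); the trough alone is far too imprecise (~37%).
Targeting the *underlying* AUC — the trapezoid of the individual predicted
curve, which excludes residual assay error — the same four-point design does
better, because noise in the reference no longer counts against it:

```r
print(loocv_evaluate(cohort, model, designs[[1]], refit = FALSE,
                     fitted = fit, target = "underlying"))
#> LSS C0, C2, C3, C4 [underlying AUC, N=10]: 95th PAE% 12.98 | RMSE% 6.46 (2.57, 9.73) | ME% 0.23 (-3.99, 3.75)
```

On real clinical profiles the corresponding published figures for this design
were 14% (observed) and 17% (underlying) for IV cyclosporine; here both
cross-validation and the "truth" are simulated, so numbers vary with the
seed. `fit$model` also shows the refit recovering the generating values
(CL 16.2 vs 14.8 L/h on this 10-profile seed; the shipped 50-profile
recovery experiment is much tighter).

The whole comparison — several model variants, all 255 designs per route,
both AUC targets, representative shortlists, diagnostics, manifest — is one
call:

```r
cfg <- run_config(cohort = cohort_spec(seed = 1),
                  models = list(combined = csa_structural_model("combined"),
                                additive = csa_structural_model("additive")),
                  outdir = "blss_run")
run_pipeline(cfg, verbose = TRUE)
```

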