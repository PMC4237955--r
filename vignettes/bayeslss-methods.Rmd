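---
title: "Bayesian limited sampling strategies for cyclosporine AUC: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian limited sampling strategies for cyclosporine AUC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayeslss)
```

## The problem

Cyclosporine dosing in pediatric hematopoietic stem cell transplantation is
increasingly guided by the area under the blood concentration-time curve over
one twice-daily dosing interval (AUC~0-12~, ng·h/mL) rather than by the trough
concentration alone. Measuring that AUC directly needs eight or nine blood
draws over twelve hours — impractical for children. A *Bayesian limited
sampling strategy* (B-LSS) replaces the full curve with one to four samples
drawn within a few hours of the dose: a population pharmacokinetic (Pop-PK)
model serves as prior, the few measured concentrations update it by empirical
Bayes (MAP) estimation of the subject's random effects, the fitted individual
curve is reconstructed on the full nine-point grid, and the trapezoidal AUC of
that reconstruction is the prediction.

`bayeslss` implements that workflow end to end: the concentration model, the
population model machinery, a nonlinear mixed-effects estimator, the
exhaustive design search with leave-one-out cross-validation (LOOCV), the
prediction-error indices used to rank designs, and a cohort simulator that
reproduces the statistical structure of the clinical study the methodology
comes from (whose raw patient data are not public).

## Structural model

Drug disposition follows a two-compartment model with first-order elimination,
parameterised by clearance CL (L/h), central and peripheral volumes Vc and Vp
(L), and inter-compartmental clearance Q (L/h). Intravenous doses enter the
central compartment by zero-order infusion (2 h in the clinical protocol);
oral doses enter a depot compartment and are absorbed at first order (KA,
1/h) after a lag time ALAG (h), scaled by bioavailability F. Setting
`Q = Vp = 0` collapses the model to one compartment, which the package
supports for toy problems and oracles.

Concentrations are computed from the analytic bi-exponential solution, not an
ODE solver. Steady state under repeated dosing at interval τ = 12 h is the
geometric accumulation of each exponential dose tail,
$\sum_{n\ge1} e^{-\lambda(t+n\tau)} = e^{-\lambda t}\,e^{-\lambda\tau}/(1-e^{-\lambda\tau})$,
added to the current-interval piecewise solution; the test suite pins this
against a brute-force superposition of 200 past doses (agreement ≤ 1e-8
relative) and against a stiff ODE integrator on random parameter draws
(≤ 1e-6 relative). Trough continuity C(0) = C(τ) holds by construction.

Numerical edge cases: nearly equal disposition eigenvalues
(|λ₁ − λ₂| < 1e-10·λ₁) and an absorption constant colliding with an
eigenvalue are separated by a 1e-8 relative perturbation, avoiding the
removable singularity in the bi-exponential coefficients; non-finite outputs
raise immediately rather than propagate.

Units are fixed package-wide: dose mg, volumes L, times h, concentrations
exported as ng/mL (×1000 from the internal mg/L), AUC as ng·h/mL — the scale
clinical cyclosporine assays report on.

## Population model

Individual parameters follow the exponential inter-individual variability
(IIV) model θᵢ = θ·exp(ηᵢ) with random effects on CL, Q, KA and F. The Vc
random effect is a fixed multiple of the CL one (η_Vc = s·η_CL; the published
structural fit reports s = 0.86 with combined error, 1.02 with additive), and
η_CL, η_Q are correlated (0.44 / 0.48). Published IIV percentages are read as
approximate CVs of this model, i.e. ω-SD = IIV%/100 — the standard
pharmacometric convention. ALAG and Vp carry no random effect.

Individual bioavailability is truncated at 1: the exponential IIV model would
otherwise produce F > 1 for roughly 6% of subjects at the published F = 0.61
with 32% IIV, and a fraction cannot exceed one. The truncation is applied
identically in simulation and estimation, so the fitted model matches the
generating process.

Covariates act multiplicatively on the typical values, so term order is
irrelevant: allometric weight scaling first — (WT/35 kg)^0.75 on clearances,
(WT/35 kg)^1 on volumes, the pediatric convention — then linear
(1 + β(X − X_med)), power ((X/X_med)^β), exponential (exp(β(X − X_med))) or
categorical (1 + β_level) terms. The built-in final covariate model
(`csa_final_model()`) carries the published coefficient table under a
documented default mapping; the source table does not state each
relationship's functional form or centering median, so the mapping is plain
overridable data. Two choices deserve note: the age effects on CL and Vc are
encoded as power terms because the printed coefficients (−0.32, −0.39 per
year) would drive a linear parameterisation negative within the cohort's age
range; and the third lag-time covariate is mapped to age rather than a second
time-post-transplantation term, which would violate the one-term-per-pair
rule (age is among the published candidate covariates for the lag).

Residual error follows C_obs = C_pred(1 + ε₁) + ε₂ with proportional ε₁ and
additive ε₂ (variance v = σ_prop²·C_pred² + σ_add²). The two published
structural variants are built in: combined error (17.5% + 15 ng/mL), which
performed best for IV profiles, and purely additive (100 ng/mL), best for
oral profiles.

## Synthetic cohorts

`generate_dataset()` emulates the study conditions: 23 IV + 39 PO
steady-state profiles by default, sampled on the nominal nine-point grids
(pre-dose plus 2, 2.5, 3, 4, 6, 8, 10, 12 h IV; pre-dose plus 0.5, 1, 1.5, 2,
3, 4, 8, 12 h PO), doses at the published medians (2.5 / 4.2 mg/kg/day split
twice daily, rounded to 1 mg), covariates within the published ranges, and
assay limits of 30 and 1500 ng/mL (values outside are retained and flagged;
an optional drop mode removes below-quantification records while preserving
the ≥ 7-points inclusion rule). The IV grid deserves a note: the protocol
text lists eight IV times, but the design tables use a 2.5 h sample and the
search is described over nine points, so the nine-point grid including 2.5 h
is adopted.

Weight is log-uniform within the published range (8–83 kg), and age is
derived from weight by inverting a pediatric growth curve
(WT ≈ 10·AG^0.647 kg) with log-normal noise, clamped to the published age
range. Coupling the two avoids 10 kg adolescents; deriving age rather than
weight keeps the weight marginal exactly log-uniform, at the cost that age is
not marginally uniform. Other covariates are uniform within their ranges.

The generator writes a NONMEM-style rectangular dataset (ID, TIME, AMT, RATE,
EVID, MDV, DV, CMT plus covariate columns) and a ground-truth sidecar holding
each subject's true parameters, random effects, noise-free concentrations and
residual draws — sufficient to replay every observed value exactly, which the
tests do.

What the simulator does *not* emulate: sampling-time deviations from the
nominal grid, repeated profiles per patient (profiles are exchangeable),
dropout, dose titration across occasions, and any real-data pathology beyond
the stated error model. Passing tests on these cohorts therefore validate the
machinery under the model's own assumptions, not the clinical performance of
the published strategies.

## Estimation

**MAP.** Given a population model, a subject's random effects minimise

$$\ell(\eta) = \sum_j \left[ \frac{(y_j - f_j(\eta))^2}{v_j(\eta)} + \log v_j(\eta) \right] + \eta^\top \Omega^{-1} \eta,$$

with f the steady-state prediction and v the residual variance at f
("interaction"). The minimiser is a safeguarded Gauss-Newton iteration with
step halving, started at η = 0 plus deterministic ±0.5 SD perturbations;
IV-only profiles carry no information on η_KA and η_F, whose optimum is
pinned at the prior mode and whose Jacobian columns are skipped. Convergence
is declared at gradient norm 1e-6 (1e-7 inside population fits) or on
objective/step stagnation. One subtlety the tests document: with
proportional error the log v(η) term pulls the noise-free optimum slightly
below the data (about −2.5% in AUC at the published sigmas); with additive
error the prior and likelihood share the optimum exactly.

**Population fit.** `fit_population()` maximises a Laplace approximation of
the marginal likelihood: for each subject, −2 log ∫ p(y|η) p(η) dη is
approximated at the MAP η̂ with a Gauss-Newton (FOCE-like) Hessian
J^⊤V^{-1}J + Ω^{-1}, giving

$$\mathrm{OFV} = \sum_i \left[ \ell_i(\hat\eta_i) + n_i \log 2\pi + \log\det\Omega + \log\det(J_i^\top V_i^{-1} J_i + \Omega^{-1}) \right].$$

The OFV convention includes all constants, so differences between nested
fits follow the usual chi-square calculus; absolute OFVs are *not* expected
to match any particular software's printed values. Parameters are estimated
on unconstrained scales (log for positive quantities, logit for F, atanh for
the CL–Q correlation), with ω variances floored at 1e-8 and residual SDs
bounded below at 1e-3 so exactly noise-free data cannot push log σ to −∞.
The inner MAP always restarts from η = 0, which makes the outer objective a
deterministic smooth function of the population parameters — a warm-start
cache would make it path-dependent and corrupt finite-difference gradients.
The outer optimiser (PORT, via `nlminb`) runs with a disposition-only pooled
pre-fit for starting values and up to three restart cycles, which routinely
escape premature "false convergence" stops. KA, ALAG and F are held fixed
when the data contain no oral profiles.

Validation: on six independently seeded 50-profile cohorts (25 IV + 25 PO)
generated at the published structural values and refit from generic starts,
the median absolute relative error was 5.3% for CL, 4.3% for F and 0.9% for
ALAG, with worst cases 9.2%, 16% and 6.2%; KA is the noisiest parameter
(up to ~40%), as expected for an absorption constant with 83% IIV informed
by 25 oral profiles. The acceptance-test tolerances (12% CL, 10% ALAG, 25% F)
are calibrated from that spread. Restarting a fit at the generating values
reproduces the same optimum, so the spread is sampling noise of the cohort
size, not optimiser error.

**Model comparison.** `lrt_compare()` computes the chi-square threshold at
the requested level (6.63 at p = 0.01, 7.87 at p = 0.005 for one degree of
freedom) rather than hard-coding it, and flags fits where the full model
lands above the reduced one. `covariate_search()` runs forward inclusion at
p = 0.01 and backward elimination at p = 0.005 with a full audit trail; ties
break lexicographically by (parameter, covariate) for reproducibility, and a
candidate whose fit fails is skipped, not fatal.

## Design search and evaluation

`enumerate_lss()` produces all 255 subsets of one to four points from a
nine-point grid, ordered by size then lexicographically. `loocv_evaluate()`
implements the cross-validation: each profile is left out, the population
model is refit to the remainder (`refit = TRUE`, warm-started from the
full-data fit; `refit = FALSE` reuses the full-data fit — a fast,
documented approximation that converges to the same indices as residual
noise vanishes), the left-out profile's AUC is predicted from each design by
MAP, and relative errors E% against the reference AUC are aggregated:

- ME% (mean relative error), RMSE% (root mean square), and the 95th
  percentile of |E|% (95th PAE%), the clinically favoured index;
- error-category counts (E% below −20, within ±20, above +20);
- min, max and moment skewness, since relative errors mislead on strongly
  asymmetric distributions;
- percentile-bootstrap confidence intervals for ME% and RMSE% (2000
  resamples, seeded, run on a private RNG stream so callers' seeds are
  untouched). The source tables print CIs without naming a method; the
  bootstrap is assumption-free and reproducible.

The 95th PAE% uses linear interpolation between order statistics (R's
default quantile definition), pinned by an independent sort-and-interpolate
oracle in the tests; the source does not state its convention.

Two reference AUCs are supported. The *observed* AUC is the trapezoid over
the measured concentrations on the full grid — like-for-like with the
predicted trapezoid. The *underlying* AUC integrates the individual
predicted (IPRED) curve obtained by MAP on all nine observations: a
residual-error-free exposure estimate. On simulated cohorts, designs predict
the underlying AUC better than the observed one in the clear majority of
cases — residual noise in the reference inflates apparent prediction error —
mirroring the finding that motivated the distinction. Incidentally, the
simulated IV cohorts reproduce the published headline numbers closely (the
practical four-point design C0, C2, C3, C4 lands near 14–15% observed-target
95th PAE%).

`select_representatives()` rebuilds the published shortlist logic per design
size: the globally best design by 95th PAE%, then the best three among
clinically practical designs (pre-dose sample included, nothing later than
4 h post-dose), de-duplicated, ties broken by RMSE%, then earlier last
sample, then label; the one-point subgroup contributes at most two rows.

## Pipeline and reproducibility

`run_config()` + `run_pipeline()` tie the stages together: simulate, fit
each model variant, sweep designs per route and target, shortlist, and write
publication-shaped CSVs plus per-observation PRED/IPRED diagnostics and a
manifest of seeds, versions and timings. Every output is a deterministic
function of the configuration: the cohort seed drives simulation and the run
seed drives the bootstrap streams, so re-running a configuration reproduces
every file byte for byte (a test asserts this). Model-variant failures are
isolated and recorded in the manifest. Configurations and model
specifications round-trip losslessly through YAML, and a thin command-line
wrapper (`inst/cli/bayeslss.R`) exposes simulate / fit / lss-search / run /
demo subcommands over the same functions.

Problem sizes in the shipped tests are chosen to exercise every code path at
desk scale: the recovery experiment uses the 50-profile cohort size of the
headline experiment; cross-validation tests use 6–12-profile cohorts; the
full-factorial 255-design sweep runs in the fast `refit = FALSE` mode, with
per-fold refits reserved for the noise-free null where the result is exact.

## Known limitations

- The estimator is a Laplace/FOCE-class approximation: absolute OFVs are on
  their own convention, and parameters with large IIV on few profiles (KA
  here) carry visible finite-sample spread. Bioavailability estimates from
  25 oral profiles with 32% IIV scatter by roughly ±10–15% across simulation
  seeds — an irreducible feature of the design size, worth keeping in mind
  when reading single-seed results.
- Standard errors come from a numerical Hessian of the OFV (delta method on
  the transformed scales); no bootstrap SEs.
- No inter-occasion variability, no Michaelis–Menten elimination, no
  transit-compartment absorption, no three-compartment disposition, and no
  regression-based (multiple linear regression) LSS — the Bayesian route is
  the point here.
- Below-quantification handling is flag-or-drop; no likelihood-based
  censoring treatment.
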