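# Shared fixtures, built in code.

# One-compartment oral toy model with two active random effects (CL, KA):
# small enough for dense grid-search oracles.
toy_po_model <- function(sigma_add = 10, sigma_prop = 0) {
  population_model(
    theta = list(CL = 5, Vc = 20, Q = 0, Vp = 0, KA = 1.2, ALAG = 0, F = 0.8),
    iiv = c(CL = 0.3, Q = 0, KA = 0.4, F = 0),
    error = error_model(
      if (sigma_prop > 0) "combined" else "additive",
      sigma_add = sigma_add, sigma_prop = sigma_prop))
}

# Copy of a model with residual error switched off (noise-free generation).
noise_free <- function(pop) {
  pop$error$sigma_add <- 0
  pop$error$sigma_prop <- 0
  pop
}

ref_cov <- function(WT = 35) covariate_vector(WT = WT, AG = 11, TPT = 1,
                                              AP = 100)

# Small simulated cohorts for estimation / LSS tests.
small_cohort <- function(n_iv, n_po, seed, model, ...) {
  generate_dataset(cohort_spec(n_iv_profiles = n_iv, n_po_profiles = n_po,
                               seed = seed, ...), model = model)
}

# Toy one-compartment oral cohort (no covariate model, all subjects 20 kg).
toy_cohort <- function(n, seed, model = toy_po_model()) {
  spec <- cohort_spec(n_iv_profiles = 0, n_po_profiles = n, seed = seed,
                      ranges_po = list(WT = c(20, 20), AG = c(6, 6),
                                       TPT = c(1, 1), AP = c(100, 100)))
  generate_dataset(spec, model = model)
}

# Fast controls for population fits inside tests.
fast_fit <- list(iter.max = 120, eval.max = 400, rel.tol = 1e-7,
                 restarts = 2)

# Independent ODE oracle (deSolve): two-compartment disposition with
# zero-order infusion or lagged first-order absorption, single dose.
ode_oracle <- function(p, reg, times) {
  k10 <- p$CL / p$Vc
  k12 <- if (p$Vp > 0) p$Q / p$Vc else 0
  k21 <- if (p$Vp > 0) p$Q / p$Vp else 0
  if (reg$route == "IV") {
    R <- reg$dose_amount / reg$infusion_duration
    de <- function(t, y, parms) {
      inp <- if (t < reg$infusion_duration) R else 0
      list(c(0,
             inp - (k10 + k12) * y[2] + k21 * y[3],
             k12 * y[2] - k21 * y[3]))
    }
    tgrid <- sort(unique(c(0, times, reg$infusion_duration)))
    out <- deSolve::lsoda(c(depot = 0, cent = 0, peri = 0), tgrid, de, NULL,
                          rtol = 1e-11, atol = 1e-11)
  } else {
    de <- function(t, y, parms) {
      list(c(-p$KA * y[1],
             p$KA * y[1] - (k10 + k12) * y[2] + k21 * y[3],
             k12 * y[2] - k21 * y[3]))
    }
    ev <- data.frame(var = "depot", time = p$ALAG,
                     value = p$F * reg$dose_amount, method = "add")
    tgrid <- sort(unique(c(0, times, p$ALAG)))
    out <- deSolve::lsoda(c(depot = 0, cent = 0, peri = 0), tgrid, de, NULL,
                          rtol = 1e-11, atol = 1e-11,
                          events = list(data = ev))
  }
  1000 * out[match(times, out[, 1]), "cent"] / p$Vc
}

# Random-but-plausible structural parameter draw for property tests.
random_params <- function() {
  structural_params(
    CL = exp(runif(1, log(2), log(40))),
    Vc = exp(runif(1, log(8), log(80))),
    Q = exp(runif(1, log(2), log(40))),
    Vp = exp(runif(1, log(20), log(300))),
    KA = exp(runif(1, log(0.2), log(3))),
    ALAG = runif(1, 0, 0.8),
    F = runif(1, 0.2, 1))
}
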