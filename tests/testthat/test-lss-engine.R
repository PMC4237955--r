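test_that("design enumeration yields the exact subset counts in deterministic order", {
  grid <- nominal_grid("IV")
  designs <- enumerate_lss(grid, 4)
  expect_length(designs, 255)
  sizes <- table(vapply(designs, function(d) length(d$times), 0L))
  expect_equal(unname(c(sizes)), c(9L, 36L, 84L, 126L))
  expect_length(enumerate_lss(grid, 1), 9)
  # ordered by size then lexicographically by time
  expect_equal(designs[[1]]$times, 0)
  expect_equal(designs[[10]]$times, c(0, 2))
  expect_equal(designs[[255]]$times, c(6, 8, 10, 12))
  expect_error(enumerate_lss(c(0, 2, 2), 4), "duplicate")
  expect_error(lss_design(c(0, 2, 3, 4, 6)), "1 to 4")
  expect_error(lss_design(c(2, 2)), "unique")
})

test_that("error indices match hand arithmetic and a sort-and-interpolate oracle", {
  z <- error_indices(rep(0, 10), n_boot = 50)
  expect_equal(z$me, 0)
  expect_equal(z$rmse, 0)
  expect_equal(z$pae95, 0)
  e <- error_indices(c(10, -10, 20), n_boot = 200)
  expect_equal(round(e$me, 2), 6.67)
  expect_equal(round(e$rmse, 2), 14.14)
  expect_equal(unname(e$categories), c(0L, 3L, 0L))
  # 95th percentile by linear interpolation of order statistics
  pae_oracle <- function(x) {
    x <- sort(abs(x))
    h <- (length(x) - 1) * 0.95 + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  expect_equal(error_indices(c(10, 10, 20), n_boot = 50)$pae95,
               pae_oracle(c(10, 10, 20)))
  set.seed(14)
  for (i in 1:20) {
    E <- rnorm(sample(3:40, 1), sd = 15)
    idx <- error_indices(E, n_boot = 50)
    expect_equal(idx$pae95, pae_oracle(E))
    expect_gte(idx$rmse, abs(idx$me))          # RMSE% >= |ME%|
    expect_lte(idx$pae95, max(abs(E)) + 1e-12) # 95th PAE% <= max |E|
    expect_equal(sum(idx$categories), idx$n)
  }
  expect_error(error_indices(numeric(0)), "at least one")
})

test_that("bootstrap confidence intervals are seeded and leave the caller's RNG alone", {
  E <- c(5, -3, 12, 8, -7, 2, 15, -1)
  a <- error_indices(E, boot_seed = 7)
  b <- error_indices(E, boot_seed = 7)
  expect_identical(a$me_ci, b$me_ci)
  c2 <- error_indices(E, boot_seed = 8)
  expect_false(identical(a$me_ci, c2$me_ci))
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(error_indices(E, boot_seed = 1)); x2 <- runif(1)
  expect_identical(x1, x2)
  expect_true(a$me_ci[1] <= a$me && a$me <= a$me_ci[2])
})

test_that("AUC prediction is self-consistent on noise-free profiles", {
  # evaluation model with a small residual SD: on exact data the likelihood
  # dominates the prior and MAP recovers the generating individual
  pop <- csa_structural_model("additive")
  pop$error$sigma_add <- 1
  cov <- ref_cov()
  reg <- dosing_regimen("IV", 44, 2)
  grid <- nominal_grid("IV")
  ind <- individual_params(typical_params(pop, cov),
                           c(CL = 0.2, Q = -0.1), pop$vc_slope)
  clean <- steady_state_concentration(ind, reg, grid)
  prof <- concentration_profile("s", grid, clean, reg)
  truth_auc <- trapezoidal_auc(grid, clean)
  # the full 9-point "design" reproduces the underlying AUC
  full9 <- predict_auc(pop, prof, cov, grid)
  expect_lt(abs(full9$auc - truth_auc) / truth_auc, 0.001)
  expect_lt(abs(full9$auc - underlying_auc(pop, prof, cov)) /
            full9$auc, 1e-9)  # identical computations by construction
  # a single pre-dose sample still returns a finite positive AUC (shrinkage)
  c0 <- predict_auc(pop, prof, cov, lss_design(0))
  expect_true(is.finite(c0$auc) && c0$auc > 0)
  # underlying AUC equals observed AUC on noise-free data
  expect_lt(abs(underlying_auc(pop, prof, cov) - truth_auc) / truth_auc,
            0.001)
})

test_that("the end-to-end design AUC matches a hand-built MAP + trapezoid oracle", {
  pop <- toy_po_model(sigma_add = 12)
  ds <- toy_cohort(4, seed = 44)
  s <- bayeslss:::as_subjects(ds)[[1]]
  design <- lss_design(c(0.5, 2, 8))
  got <- predict_auc(pop, s$profile, s$cov, design)$auc

  # oracle: dense grid search over the two active effects, then predict the
  # full grid from public functions and integrate by hand
  typ <- typical_params(pop, s$cov)
  om <- omega_matrix(pop)
  keep <- match(design$times, s$times)
  obj <- function(ecl, eka) {
    ind <- individual_params(typ, c(CL = ecl, KA = eka), 0)
    f <- steady_state_concentration(ind, s$regimen, s$times[keep])
    v <- residual_variance(pop$error, f)
    sum((s$y[keep] - f)^2 / v + log(v)) +
      ecl^2 / om["CL", "CL"] + eka^2 / om["KA", "KA"]
  }
  gr <- seq(-1, 1, by = 0.01)
  vals <- outer(gr, gr, Vectorize(obj))
  best <- which(vals == min(vals), arr.ind = TRUE)
  ind <- individual_params(typ, c(CL = gr[best[1]], KA = gr[best[2]]), 0)
  oracle <- trapezoidal_auc(s$times,
                            steady_state_concentration(ind, s$regimen, s$times))
  expect_lt(abs(got - oracle) / oracle, 0.005)
})

test_that("cross-validated indices equal a naive-loop re-implementation", {
  pop <- toy_po_model(sigma_add = 12)
  ds <- toy_cohort(12, seed = 55)
  fit <- fit_population(ds, pop, control = fast_fit)
  designs <- list(lss_design(c(0.5, 2, 8)), lss_design(c(0, 3)))
  evals <- loocv_evaluate(ds, pop, designs, refit = FALSE, fitted = fit,
                          n_boot = 50)

  subs <- bayeslss:::as_subjects(ds)
  for (j in seq_along(designs)) {
    E <- vapply(subs, function(s) {
      ref <- trapezoidal_auc(s$times, s$y)
      mp <- map_estimate(fit$model, s$profile, s$cov,
                         design = designs[[j]]$times)
      pred <- trapezoidal_auc(s$times, mp$fitted)
      100 * (pred - ref) / ref
    }, 0)
    expect_equal(evals[[j]]$E, E, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(evals[[j]]$me, mean(E))
    expect_equal(evals[[j]]$rmse, sqrt(mean(E^2)))
    expect_equal(evals[[j]]$pae95,
                 unname(quantile(abs(E), 0.95, type = 7)))
  }

  # permuting profile order leaves every index unchanged
  perm <- ds$data[order(-ds$data$ID, ds$data$TIME, -ds$data$EVID), ]
  evals_p <- loocv_evaluate(perm, pop, designs, refit = FALSE, fitted = fit,
                            n_boot = 50)
  for (j in seq_along(designs)) {
    expect_equal(sort(evals_p[[j]]$E), sort(evals[[j]]$E), tolerance = 1e-10)
    expect_equal(evals_p[[j]]$pae95, evals[[j]]$pae95, tolerance = 1e-10)
  }
})

test_that("noise-free cohorts give near-exact cross-validated prediction for rich designs", {
  gen <- noise_free(toy_po_model())
  ds <- toy_cohort(6, seed = 66, model = gen)
  # evaluation model keeps a small additive error; the data are exact
  pop <- toy_po_model(sigma_add = 5)
  fit_model <- pop
  fit <- fit_population(ds, fit_model, control = fast_fit)
  rich <- lss_design(c(0, 1, 2, 8))
  poor <- lss_design(c(0, 12))
  ev <- loocv_evaluate(ds, fit_model, list(rich, poor), refit = FALSE,
                       fitted = fit, n_boot = 50)
  expect_lt(ev[[1]]$pae95, 1)
  # the full-grid design is at least as good as any sub-design here
  full <- loocv_evaluate(ds, fit_model, lss_design(nominal_grid("PO")[1:4]),
                         refit = FALSE, fitted = fit, n_boot = 50)
  expect_lte(full$pae95, ev[[2]]$pae95 + 1e-9)
})

test_that("representative selection follows the published shortlist rules", {
  # constructed evaluation table with a known ordering
  tab <- data.frame(
    design = c("C2, C6", "C0, C2", "C0, C3", "C0, C4", "C0, C8",
               "C6", "C0", "C3"),
    size = c(2, 2, 2, 2, 2, 1, 1, 1),
    includes_c0 = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    tmax = c(6, 2, 3, 4, 8, 6, 0, 3),
    n = 10, pae95 = c(9, 14, 12, 13, 11, 24, 37, 30),
    rmse = c(5, 8, 7, 7.5, 6, 12, 20, 15), me = 0,
    n_below = 0, n_within = 10, n_above = 0,
    target = "observed", stringsAsFactors = FALSE)
  sel <- select_representatives(tab, window_hours = 4, route = "IV")
  two <- sel[sel$size == 2, ]
  # global best first, then the best C0-containing <= 4 h designs
  expect_equal(two$design, c("C2, C6", "C0, C3", "C0, C4", "C0, C2"))
  one <- sel[sel$size == 1, ]
  # the one-point subgroup only has C0 in the restricted set: two rows
  expect_equal(one$design, c("C6", "C0"))
  expect_true(nrow(sel) <= 14)

  # all tied: selection falls back to deterministic label order
  tied <- tab
  tied$pae95 <- 10
  tied$rmse <- 5
  tied$tmax <- 2
  s1 <- select_representatives(tied)
  s2 <- select_representatives(tied[sample(nrow(tied)), ])
  expect_equal(s1$design, s2$design)
})

test_that("a full sweep shortlist caps at 14 rows per route", {
  set.seed(31)
  designs <- enumerate_lss(nominal_grid("IV"), 4)
  tab <- data.frame(
    design = vapply(designs, `[[`, "", "label"),
    size = vapply(designs, function(d) length(d$times), 0),
    includes_c0 = vapply(designs, function(d) 0 %in% d$times, TRUE),
    tmax = vapply(designs, function(d) max(d$times), 0),
    n = 23, pae95 = runif(255, 5, 60), rmse = runif(255, 3, 30), me = 0,
    n_below = 0, n_within = 23, n_above = 0, target = "observed",
    stringsAsFactors = FALSE)
  sel <- select_representatives(tab, route = "IV")
  expect_lte(nrow(sel), 14)
  expect_equal(sort(unique(sel$size)), 1:4)
  expect_lte(sum(sel$size == 1), 2)
  # every restricted pick includes C0 within the 4 h window
  restricted <- sel[sel$rank > 1, ]
  expect_true(all(restricted$includes_c0 & restricted$tmax <= 4))
})

test_that("underlying AUC is less noise-sensitive than the observed trapezoid", {
  # additive-noise setting with the matching additive-error model: the MAP
  # filter should damp residual noise relative to the raw trapezoid
  pop <- csa_structural_model("additive")
  cov <- ref_cov()
  reg <- dosing_regimen("IV", 44, 2)
  grid <- nominal_grid("IV")
  ind <- individual_params(typical_params(pop, cov), c(CL = 0.15, Q = 0.1),
                           pop$vc_slope)
  clean <- steady_state_concentration(ind, reg, grid)
  auc_clean <- trapezoidal_auc(grid, clean)
  und_clean <- underlying_auc(pop, concentration_profile("c", grid, clean, reg),
                              cov)
  set.seed(19)
  d_obs <- d_und <- numeric(10)
  for (r in 1:10) {
    noisy <- pmax(clean + rnorm(9, 0, 100), 0)
    prof <- concentration_profile("n", grid, noisy, reg)
    d_obs[r] <- abs(trapezoidal_auc(grid, noisy) - auc_clean)
    d_und[r] <- abs(underlying_auc(pop, prof, cov) - und_clean)
  }
  expect_lt(mean(d_und), mean(d_obs))
})
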