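test_that("typical parameters apply allometry with the stated exponents", {
  pop <- csa_structural_model("combined")
  at_ref <- typical_params(pop, ref_cov(WT = 35))
  expect_equal(at_ref$CL, 14.82)
  expect_equal(at_ref$Vc, 31.8)
  doubled <- typical_params(pop, ref_cov(WT = 70))
  expect_equal(doubled$CL, 14.82 * 2^0.75)
  expect_equal(doubled$Q, 13.49 * 2^0.75)
  expect_equal(doubled$Vc, 31.8 * 2)
  expect_equal(doubled$Vp, 104.6 * 2)
  # absorption parameters are not weight-scaled
  expect_equal(doubled$KA, at_ref$KA)
  expect_equal(doubled$F, at_ref$F)
})

test_that("covariate terms multiply in, in any order, against a hand expansion", {
  base <- list(CL = 10, Vc = 30, Q = 0, Vp = 0, KA = 1, ALAG = 0.3, F = 0.6)
  terms <- list(
    covariate_term("CL", "AG", "linear", coef = -0.32, center = 11),
    covariate_term("CL", "AP", "exponential", coef = 0.001, center = 100),
    covariate_term("Vc", "AG", "power", coef = -0.39, center = 11),
    covariate_term("ALAG", "FORM", "categorical",
                   coef = c(suspension = -0.39, capsule = -0.022)))
  cov <- covariate_vector(WT = 20, AG = 12, TPT = 1, AP = 150,
                          FORM = "suspension")
  hand_CL <- 10 * (1 - 0.32 * (12 - 11)) * exp(0.001 * (150 - 100))
  hand_Vc <- 30 * (12 / 11)^-0.39
  hand_ALAG <- 0.3 * (1 - 0.39)
  for (ord in list(1:4, 4:1, c(2, 4, 1, 3))) {
    pop <- population_model(base, covariates = terms[ord])
    p <- typical_params(pop, cov)
    expect_equal(p$CL, hand_CL)
    expect_equal(p$Vc, hand_Vc)
    expect_equal(p$ALAG, hand_ALAG)
    expect_equal(p$F, 0.6)   # untouched
  }
  # the linear term with coef -0.32 and X - Xmed = 1 is exactly a 0.68 factor
  pop1 <- population_model(base, covariates = terms[1])
  expect_equal(typical_params(pop1, cov)$CL, 10 * 0.68)
  # reference category multiplies by one
  pop4 <- population_model(base, covariates = terms[4])
  expect_equal(typical_params(pop4, ref_cov())$ALAG, 0.3)
})

test_that("covariate terms that drive a parameter non-positive raise", {
  base <- list(CL = 10, Vc = 30, Q = 0, Vp = 0, KA = 1, ALAG = 0.3, F = 0.6)
  pop <- population_model(base, covariates = list(
    covariate_term("CL", "AG", "linear", coef = -0.32, center = 11)))
  expect_error(typical_params(pop, covariate_vector(WT = 20, AG = 17)),
               "non-positive")
  expect_error(population_model(base, covariates = list(
    covariate_term("CL", "AG", "linear", coef = -0.32, center = 11),
    covariate_term("CL", "AG", "power", coef = 1, center = 11))),
    "at most once")
})

test_that("individual parameters follow the exponential IIV model", {
  typ <- structural_params(CL = 10, Vc = 30, Q = 5, Vp = 50, KA = 1,
                           ALAG = 0.4, F = 0.6)
  same <- individual_params(typ, c(CL = 0, Q = 0, KA = 0, F = 0), 0.86)
  expect_equal(unclass(same), unclass(typ))
  dbl <- individual_params(typ, c(CL = log(2)), 0)
  expect_equal(dbl$CL, 20)
  # the Vc random effect is a fixed multiple of the CL one
  sl <- individual_params(typ, c(CL = 0.1), 0.86)
  expect_equal(sl$Vc, 30 * exp(0.086))
  # no random effect on ALAG / Vp
  wild <- individual_params(typ, c(CL = 1, Q = 1, KA = 1, F = 1), 0.86)
  expect_equal(wild$ALAG, 0.4)
  expect_equal(wild$Vp, 50)
  # bioavailability is truncated at 1
  expect_equal(wild$F, 1)
})

test_that("residual variance follows the combined error model", {
  comb <- error_model("combined", sigma_add = 15, sigma_prop = 0.175)
  expect_equal(residual_variance(comb, 0), 15^2)
  expect_equal(residual_variance(comb, 100), 531.25)
  addm <- error_model("additive", sigma_add = 100)
  expect_equal(residual_variance(addm, c(0, 50, 1000)), rep(1e4, 3))
  prop <- error_model("proportional", sigma_prop = 0.2)
  expect_equal(residual_variance(prop, 50), 100)
  # monotone non-decreasing in the prediction for prop/combined kinds
  pr <- seq(0, 1500, 50)
  expect_true(all(diff(residual_variance(comb, pr)) >= 0))
  expect_error(residual_variance(comb, -1), ">= 0")
  expect_error(error_model("additive", sigma_prop = 0.1), "additive")
})

test_that("expanded omega is positive semidefinite with the stated correlation", {
  for (variant in c("combined", "additive")) {
    om <- omega_matrix(csa_structural_model(variant))
    ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) >= 0)
    expect_true(!inherits(try(chol(om), silent = TRUE), "try-error"))
  }
  om <- omega_matrix(csa_structural_model("combined"))
  expect_equal(om["CL", "Q"], 0.44 * 0.31 * 0.80)
  expect_equal(unname(diag(om)), c(0.31, 0.80, 0.83, 0.32)^2)
  expect_error(population_model(
    list(CL = 1, Vc = 1, Q = 1, Vp = 1, KA = 1, ALAG = 0, F = 1),
    corr_cl_q = 1.2), "corr")
})

test_that("model specifications round-trip losslessly through YAML", {
  for (pop in list(csa_structural_model("combined"),
                   csa_structural_model("additive"),
                   csa_final_model(),
                   toy_po_model())) {
    path <- tempfile(fileext = ".yaml")
    write_model_spec(pop, path)
    back <- read_model_spec(path)
    expect_equal(back$theta, pop$theta)
    expect_equal(back$iiv, pop$iiv)
    expect_equal(back$corr_cl_q, pop$corr_cl_q)
    expect_equal(back$vc_slope, pop$vc_slope)
    expect_equal(unclass(back$error), unclass(pop$error))
    expect_equal(length(back$covariates), length(pop$covariates))
    if (length(pop$covariates))
      expect_equal(lapply(back$covariates, unclass),
                   lapply(pop$covariates, unclass))
    expect_equal(back$allometry, pop$allometry)
    unlink(path)
  }
})
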