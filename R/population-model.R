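# Population model: fixed effects + covariate model + between-subject random
# effects + residual error. Individual parameters follow the exponential
# inter-individual variability (IIV) model theta_i = theta * exp(eta_i), with
# random effects on CL, Q, KA and F; the Vc random effect is a fixed scalar
# multiple of the CL random effect (eta_Vc = vc_slope * eta_CL), and ALAG and
# Vp carry no random effect.

.ETA_NAMES <- c("CL", "Q", "KA", "F")

#' Residual error model
#'
#' Observation model `C_obs = C_pred * (1 + eps1) + eps2` with proportional
#' eps1 ~ N(0, sigma_prop^2) and additive eps2 ~ N(0, sigma_add^2).
#'
#' @param kind `"additive"`, `"proportional"` or `"combined"`.
#' @param sigma_add Additive error SD, ng/mL.
#' @param sigma_prop Proportional error SD, dimensionless fraction.
#' @return Object of class `error_model`.
#' @export
error_model <- function(kind = c("combined", "additive", "proportional"),
                        sigma_add = 0, sigma_prop = 0) {
  kind <- match.arg(kind)
  if (sigma_add < 0 || sigma_prop < 0) stop("error SDs must be >= 0")
  if (kind == "additive" && sigma_prop != 0)
    stop("additive error model requires sigma_prop = 0")
  if (kind == "proportional" && sigma_add != 0)
    stop("proportional error model requires sigma_add = 0")
  structure(list(kind = kind, sigma_add = sigma_add, sigma_prop = sigma_prop),
            class = "error_model")
}

#' Residual error variance at a predicted concentration
#'
#' @param err An [error_model()].
#' @param pred Predicted concentration(s), ng/mL, non-negative.
#' @return Variance(s) in (ng/mL)^2.
#' @export
residual_variance <- function(err, pred) {
  stopifnot(inherits(err, "error_model"))
  if (any(pred < 0)) stop("pred must be >= 0")
  switch(err$kind,
         additive = rep(err$sigma_add^2, length(pred)),
         proportional = err$sigma_prop^2 * pred^2,
         combined = err$sigma_prop^2 * pred^2 + err$sigma_add^2)
}

#' One covariate-parameter relationship
#'
#' @param param Target structural parameter (`"CL"`, `"Vc"`, ...).
#' @param covariate Covariate name (`"AG"`, `"AP"`, `"TPT"`, `"FORM"`, ...).
#' @param form `"linear"` (`x (1 + coef (X - center))`), `"power"`
#'   (`x (X/center)^coef`), `"exponential"` (`x exp(coef (X - center))`) or
#'   `"categorical"` (`x (1 + coef[level])`, reference levels omitted from
#'   `coef` multiply by 1).
#' @param coef Coefficient; for `"categorical"`, a named vector by level.
#' @param center Centering value (the covariate median); required and positive
#'   for power/exponential forms.
#' @return Object of class `covariate_term`.
#' @export
covariate_term <- function(param, covariate,
                           form = c("linear", "power", "exponential", "categorical"),
                           coef, center = NA_real_) {
  form <- match.arg(form)
  if (form %in% c("power", "exponential") &&
      (!is.finite(center) || center <= 0))
    stop("power/exponential forms need a positive centering value")
  if (form == "categorical" && is.null(names(coef)))
    stop("categorical coef must be named by level")
  structure(list(param = param, covariate = covariate, form = form,
                 coef = coef, center = center),
            class = "covariate_term")
}

#' Subject covariates
#'
#' @param WT Body weight, kg (> 0).
#' @param AG Age at profile, years.
#' @param TPT Time post transplantation, months.
#' @param AP Alkaline phosphatase, U/L.
#' @param FORM Dosage form: `"IV"`, `"suspension"` or `"capsule"`.
#' @param SEX `"M"` or `"F"`.
#' @param ... Optional additional labs (albumin, bilirubin, AST, ALT, GGT, Hb,
#'   Hct, ...) available to the covariate search.
#' @return Object of class `covariate_vector`.
#' @export
covariate_vector <- function(WT, AG, TPT = 0, AP = 100, FORM = "IV",
                             SEX = "M", ...) {
  if (!is.finite(WT) || WT <= 0) stop("WT must be > 0")
  if (!is.finite(AG) || AG < 0) stop("AG must be >= 0")
  if (!is.finite(TPT) || TPT < 0) stop("TPT must be >= 0")
  if (!FORM %in% c("IV", "suspension", "capsule")) stop("unknown FORM")
  if (!SEX %in% c("M", "F")) stop("SEX must be 'M' or 'F'")
  structure(c(list(WT = WT, AG = AG, TPT = TPT, AP = AP, FORM = FORM,
                   SEX = SEX), list(...)),
            class = "covariate_vector")
}

#' Population pharmacokinetic model
#'
#' Bundles typical parameter values, the covariate model, the between-subject
#' random-effect covariance and the residual error model.
#'
#' @param theta Named numeric vector/list of typical values: `CL`, `Vc`, `Q`,
#'   `Vp`, `KA`, `ALAG`, `F` (units as in [structural_params()]).
#' @param iiv Named vector of random-effect standard deviations (approximate
#'   CV fractions of the exponential IIV model) for `CL`, `Q`, `KA`, `F`.
#'   Missing entries default to 0.
#' @param corr_cl_q Correlation between the CL and Q random effects.
#' @param vc_slope Scalar s in `eta_Vc = s * eta_CL`.
#' @param error An [error_model()].
#' @param covariates List of [covariate_term()]s; at most one term per
#'   (parameter, covariate) pair.
#' @param allometry `NULL`, or `list(ref_weight, exp_cl, exp_v)`: clearances
#'   (CL, Q) scale as `(WT/ref_weight)^exp_cl`, volumes (Vc, Vp) as
#'   `(WT/ref_weight)^exp_v`.
#' @return Object of class `population_model`.
#' @export
population_model <- function(theta, iiv = c(CL = 0, Q = 0, KA = 0, F = 0),
                             corr_cl_q = 0, vc_slope = 0,
                             error = error_model("additive"),
                             covariates = list(), allometry = NULL) {
  theta <- as.list(theta)
  need <- c("CL", "Vc", "Q", "Vp", "KA", "ALAG", "F")
  if (!all(need %in% names(theta)))
    stop("theta must name all of: ", paste(need, collapse = ", "))
  full_iiv <- stats::setNames(numeric(4), .ETA_NAMES)
  full_iiv[names(iiv)] <- unlist(iiv)
  if (any(full_iiv < 0)) stop("IIV standard deviations must be >= 0")
  if (abs(corr_cl_q) > 1) stop("corr_cl_q must lie in [-1, 1]")
  stopifnot(inherits(error, "error_model"))
  for (term in covariates) stopifnot(inherits(term, "covariate_term"))
  keys <- vapply(covariates, function(x) paste(x$param, x$covariate), "")
  if (anyDuplicated(keys))
    stop("each (parameter, covariate) pair may appear at most once")
  if (!is.null(allometry))
    stopifnot(all(c("ref_weight", "exp_cl", "exp_v") %in% names(allometry)),
              allometry$ref_weight > 0)
  pop <- structure(list(theta = theta, iiv = full_iiv, corr_cl_q = corr_cl_q,
                        vc_slope = vc_slope, error = error,
                        covariates = covariates, allometry = allometry),
                   class = "population_model")
  omega_matrix(pop)  # fail early if not positive semidefinite
  pop
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (two-compartment, first-order absorption)\n")
  cat("  theta:", paste(sprintf("%s=%.4g", names(x$theta), unlist(x$theta)),
                        collapse = " "), "\n")
  cat("  IIV sd:", paste(sprintf("%s=%.3g", names(x$iiv), x$iiv),
                         collapse = " "),
      sprintf(" corr(CL,Q)=%.2f  vc_slope=%.3g\n", x$corr_cl_q, x$vc_slope))
  cat(sprintf("  error: %s (add %.4g ng/mL, prop %.4g)\n", x$error$kind,
              x$error$sigma_add, x$error$sigma_prop))
  if (length(x$covariates))
    for (tm in x$covariates)
      cat(sprintf("  covariate: %s ~ %s (%s)\n", tm$param, tm$covariate,
                  tm$form))
  invisible(x)
}

#' Expanded random-effect covariance matrix
#'
#' 4x4 covariance of `(eta_CL, eta_Q, eta_KA, eta_F)` implied by the model's
#' standard deviations and CL-Q correlation. Raises if the matrix is not
#' positive semidefinite.
#'
#' @param pop A [population_model()].
#' @return Named 4x4 covariance matrix.
#' @export
omega_matrix <- function(pop) {
  sd <- pop$iiv
  om <- diag(sd^2, 4)
  dimnames(om) <- list(.ETA_NAMES, .ETA_NAMES)
  om["CL", "Q"] <- om["Q", "CL"] <- pop$corr_cl_q * sd["CL"] * sd["Q"]
  ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(abs(ev), 1))
    stop("expanded omega matrix is not positive semidefinite")
  om
}

# Inverse of omega with variances floored (spec: bound below at 1e-8) so the
# MAP prior stays proper when some effects are switched off.
.omega_inv <- function(pop, floor = 1e-8) {
  om <- omega_matrix(pop)
  diag(om) <- pmax(diag(om), floor)
  solve(om)
}

#' Typical individual parameters given covariates
#'
#' Applies allometric weight scaling and then every covariate term
#' multiplicatively to the population typical values. Terms commute, so their
#' order is irrelevant.
#'
#' @param pop A [population_model()].
#' @param cov A [covariate_vector()].
#' @return A [structural_params()] object.
#' @export
typical_params <- function(pop, cov) {
  stopifnot(inherits(pop, "population_model"),
            inherits(cov, "covariate_vector"))
  p <- pop$theta
  if (!is.null(pop$allometry)) {
    w <- cov$WT / pop$allometry$ref_weight
    fcl <- w^pop$allometry$exp_cl
    fv <- w^pop$allometry$exp_v
    p$CL <- p$CL * fcl
    p$Q <- p$Q * fcl
    p$Vc <- p$Vc * fv
    p$Vp <- p$Vp * fv
  }
  for (tm in pop$covariates) {
    x <- cov[[tm$covariate]]
    if (is.null(x)) stop("covariate ", tm$covariate, " missing from subject")
    mult <- switch(tm$form,
      linear = 1 + tm$coef * (x - tm$center),
      power = (x / tm$center)^tm$coef,
      exponential = exp(tm$coef * (x - tm$center)),
      categorical = {
        if (x %in% names(tm$coef)) 1 + unname(tm$coef[x]) else 1
      })
    if (!is.finite(mult) || mult <= 0)
      stop(sprintf("covariate term %s~%s drives %s non-positive (multiplier %g)",
                   tm$param, tm$covariate, tm$param, mult))
    p[[tm$param]] <- p[[tm$param]] * mult
  }
  if (p$CL <= 0 || p$Vc <= 0 || p$Q < 0 || p$Vp < 0)
    stop("covariate model drove a structural parameter non-positive")
  structural_params(CL = p$CL, Vc = p$Vc, Q = p$Q, Vp = p$Vp, KA = p$KA,
                    ALAG = p$ALAG, F = min(p$F, 1))
}

#' Individual parameters from typical values and random effects
#'
#' Exponential IIV: each parameter with a random effect is multiplied by
#' `exp(eta)`; `Vc` uses `exp(vc_slope * eta_CL)`; `ALAG` and `Vp` carry no
#' random effect. Individual bioavailability is truncated at 1 (a fraction by
#' definition).
#'
#' @param typical A [structural_params()] (output of [typical_params()]).
#' @param eta Named numeric vector with entries `CL`, `Q`, `KA`, `F`.
#' @param vc_slope Scalar linking the Vc random effect to the CL one.
#' @return A [structural_params()] object.
#' @export
individual_params <- function(typical, eta, vc_slope = 0) {
  stopifnot(inherits(typical, "structural_params"))
  e <- stats::setNames(numeric(4), .ETA_NAMES)
  e[names(eta)] <- unlist(eta)
  e <- unname(e)
  structural_params(
    CL = typical$CL * exp(e[1]),
    Vc = typical$Vc * exp(vc_slope * e[1]),
    Q = typical$Q * exp(e[2]),
    Vp = typical$Vp,
    KA = if (is.na(typical$KA)) NA_real_ else typical$KA * exp(e[3]),
    ALAG = typical$ALAG,
    F = min(typical$F * exp(e[4]), 1))
}
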