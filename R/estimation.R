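# Estimation layer.
#
# Individual (empirical Bayes / MAP) estimation minimises, over the random
# effects eta = (eta_CL, eta_Q, eta_KA, eta_F),
#
#   l(eta) = sum_j [ (y_j - f_j(eta))^2 / v_j + log v_j ] + eta' Omega^-1 eta
#
# where f is the steady-state model prediction and v the residual-error
# variance evaluated at f_j ("interaction"). Population estimation maximises a
# Laplace approximation of the marginal likelihood around each subject's MAP
# eta, with a Gauss-Newton (FOCE-like) Hessian; the reported OFV is
# -2 log-marginal-likelihood including the n log(2 pi) constant, so OFV
# differences between nested fits are chi-square distributed under the null.

.V_FLOOR <- 1e-12

`%||%` <- function(a, b) if (is.null(a)) b else a

# Plain-list individual parameters for the hot path (no S3 validation).
.eta_params <- function(typ, eta, vc_slope) {
  list(CL = typ$CL * exp(eta[1L]),
       Vc = typ$Vc * exp(vc_slope * eta[1L]),
       Q = typ$Q * exp(eta[2L]), Vp = typ$Vp,
       KA = if (is.na(typ$KA)) NA_real_ else typ$KA * exp(eta[3L]),
       ALAG = typ$ALAG,
       F = min(typ$F * exp(eta[4L]), 1))
}

# Fused steady-state concentration (ng/mL), algebraically identical to
# .conc_ss but with the disposition computed once and the single-dose and
# accumulated-tail pieces combined per exponential term. This is the hot path
# of MAP and population estimation (agreement with the reference path is
# pinned by tests).
.ss_fast <- function(CL, Vc, Q, Vp, KA, ALAG, Fb, iv, dose, tinf, tau, t) {
  k10 <- CL / Vc
  if (Q > 0) {
    k12 <- Q / Vc
    k21 <- Q / Vp
    sm <- k10 + k12 + k21
    root <- sqrt(max(sm * sm - 4 * k10 * k21, 0))
    l1 <- (sm + root) / 2
    l2 <- (sm - root) / 2
    if (l1 - l2 < 1e-10 * l1) {
      l1 <- l1 * (1 + 1e-8)
      l2 <- l2 * (1 - 1e-8)
    }
    lam <- c(l1, l2)
    cf <- c(l1 - k21, k21 - l2) / (l1 - l2)
  } else {
    lam <- k10
    cf <- 1
  }
  out <- numeric(length(t))
  if (iv) {
    R <- dose / tinf
    during <- t <= tinf
    for (i in seq_along(lam)) {
      li <- lam[i]
      ai <- R / Vc * cf[i] / li
      geo <- exp(-li * tau) / (-expm1(-li * tau))
      Ei <- exp(li * tinf)
      elt <- exp(-li * t)
      contrib <- ai * (Ei - 1) * elt * (1 + geo)   # post-infusion + tails
      contrib[during] <- ai * (1 - elt[during]) +
        ai * (Ei - 1) * geo * elt[during]
      out <- out + contrib
    }
  } else {
    ka <- KA
    while (any(abs(ka - lam) < 1e-8 * ka)) ka <- ka * (1 + 1e-8)
    k0 <- Fb * dose * ka / Vc
    pos <- t > ALAG
    rates <- c(lam, ka)
    coefs <- c(k0 * cf / (ka - lam), -k0 * sum(cf / (ka - lam)))
    for (i in seq_along(rates)) {
      ri <- rates[i]
      geo <- exp(-ri * tau) / (-expm1(-ri * tau))
      z <- coefs[i] * exp(ri * ALAG) * exp(-ri * t)
      contrib <- z * geo
      contrib[pos] <- contrib[pos] + z[pos]
      out <- out + contrib
    }
  }
  if (any(!is.finite(out)))
    stop("non-finite steady-state concentration; check parameters")
  out
}

# Model prediction (ng/mL) for a subject context at given eta.
.ctx_predict <- function(ctx, eta, times) {
  1000 * .ss_fast(ctx$typ$CL * exp(eta[1L]),
                  ctx$typ$Vc * exp(ctx$vc_slope * eta[1L]),
                  ctx$typ$Q * exp(eta[2L]), ctx$typ$Vp,
                  ctx$typ$KA * exp(eta[3L]), ctx$typ$ALAG,
                  min(ctx$typ$F * exp(eta[4L]), 1),
                  ctx$iv, ctx$dose, ctx$tinf, ctx$tau, times)
}

# Subject context: everything constant across eta.
.make_ctx <- function(pop, subject) {
  typ <- typical_params(pop, subject$cov)
  reg <- subject$regimen
  list(typ = unclass(typ), vc_slope = pop$vc_slope,
       iv = reg$route == "IV", dose = reg$dose_amount,
       tinf = if (reg$route == "IV") reg$infusion_duration else 0,
       tau = reg$interval,
       regimen = reg, times = subject$times, y = subject$y,
       sa2 = pop$error$sigma_add^2, sp2 = pop$error$sigma_prop^2)
}

.map_objective <- function(ctx, eta, idx, Oinv) {
  f <- .ctx_predict(ctx, eta, ctx$times[idx])
  v <- pmax(ctx$sp2 * f^2 + ctx$sa2, .V_FLOOR)
  r <- ctx$y[idx] - f
  sum(r^2 / v + log(v)) + c(eta %*% Oinv %*% eta)
}

# Objective that tolerates overflow at extreme eta (treated as +Inf so the
# safeguarded line search backs off instead of aborting).
.map_objective_safe <- function(ctx, eta, idx, Oinv) {
  tryCatch(.map_objective(ctx, eta, idx, Oinv), error = function(e) Inf)
}

# Safeguarded Gauss-Newton minimiser of the MAP objective. Returns the
# optimum together with the Jacobian and residual variances there (reused for
# the Laplace determinant). IV profiles carry no information on eta_KA/eta_F
# (no absorption phase), whose MAP values stay at the prior mode; their
# Jacobian columns are identically zero and are skipped.
.map_fit <- function(ctx, idx, Oinv, eta0 = numeric(4), maxit = 60,
                     gtol = 1e-6) {
  eta <- eta0
  times <- ctx$times[idx]
  y <- ctx$y[idx]
  n <- length(idx)
  active <- if (ctx$iv) 1:2 else 1:4
  # with a block-diagonal prior over {CL,Q} x {KA,F}, the IV optimum has
  # eta_KA = eta_F = 0 exactly; pin them there whatever the start
  if (ctx$iv) eta[3:4] <- 0
  h <- 1e-5
  obj <- .map_objective_safe(ctx, eta, idx, Oinv)
  if (!is.finite(obj)) {  # retreat to the prior mode if the start is wild
    eta <- numeric(4)
    obj <- .map_objective(ctx, eta, idx, Oinv)
  }
  J <- matrix(0, n, 4)
  f <- v <- NULL
  converged <- FALSE
  fill_J <- function(eta, f) {
    for (k in active) {
      ek <- eta
      ek[k] <- ek[k] + h
      J[, k] <<- (.ctx_predict(ctx, ek, times) - f) / h
    }
  }
  for (it in seq_len(maxit)) {
    f <- .ctx_predict(ctx, eta, times)
    fill_J(eta, f)
    v <- pmax(ctx$sp2 * f^2 + ctx$sa2, .V_FLOOR)
    r <- y - f
    dvdf <- 2 * ctx$sp2 * f
    dLdf <- -2 * r / v + (1 / v - r^2 / v^2) * dvdf
    grad <- drop(crossprod(J, dLdf)) + 2 * drop(Oinv %*% eta)
    if (max(abs(grad[active])) < gtol) { converged <- TRUE; break }
    H <- 2 * (crossprod(J, J / v) + Oinv)
    delta <- numeric(4)
    delta[active] <- tryCatch(
      solve(H[active, active, drop = FALSE], grad[active]),
      error = function(e) grad[active] / max(diag(H)[active]))
    alpha <- 1
    improved <- FALSE
    obj_prev <- obj
    for (ls in 1:25) {
      cand <- eta - alpha * delta
      ocand <- .map_objective_safe(ctx, cand, idx, Oinv)
      if (is.finite(ocand) && ocand < obj) {
        eta <- cand; obj <- ocand; improved <- TRUE; break
      }
      alpha <- alpha / 2
    }
    if (!improved) { converged <- max(abs(grad[active])) < 1e-3; break }
    # stagnation criteria: tiny objective gain or tiny step counts as
    # converged even when the raw gradient tolerance is unreachable (e.g.
    # near-zero residual variances on noise-free data)
    if (obj_prev - obj < 1e-10 * (abs(obj) + 1) ||
        alpha * max(abs(delta)) < 1e-9) { converged <- TRUE; break }
  }
  # refresh f/J/v at the final eta (the last accepted step moved eta)
  f <- .ctx_predict(ctx, eta, times)
  v <- pmax(ctx$sp2 * f^2 + ctx$sa2, .V_FLOOR)
  fill_J(eta, f)
  list(eta = eta, objective = obj, f = f, J = J, v = v,
       converged = converged, iterations = it)
}

#' Empirical-Bayes (MAP) estimation of one subject's random effects
#'
#' Minimises the penalised weighted residual objective over the random
#' effects, using only the observations at the design's sampling times, then
#' predicts the full sampling grid from the optimum. Started from eta = 0 plus
#' deterministic perturbed starts; the returned optimum is the best across
#' starts (its objective never exceeds the eta = 0 objective).
#'
#' @param pop A [population_model()] (the Bayesian prior).
#' @param profile A [concentration_profile()].
#' @param cov The subject's [covariate_vector()].
#' @param design Sampling times (h) to condition on: a numeric vector or an
#'   [lss_design()]; `NULL` uses every observation in the profile.
#' @param n_starts Number of optimisation starts (1 = eta 0 only; additional
#'   starts are +/- 0.5 SD perturbations).
#' @return Object of class `map_result`: `eta`, `params` (individual
#'   [structural_params()]), `fitted` (predictions at all profile times,
#'   ng/mL), `objective`, `design`, `converged`.
#' @export
map_estimate <- function(pop, profile, cov, design = NULL, n_starts = 3) {
  stopifnot(inherits(pop, "population_model"),
            inherits(profile, "concentration_profile"),
            inherits(cov, "covariate_vector"))
  dtimes <- if (is.null(design)) profile$times
            else if (inherits(design, "lss_design")) design$times
            else as.numeric(design)
  idx <- match(dtimes, profile$times)
  if (any(is.na(idx))) stop("design times absent from profile: ",
                            paste(dtimes[is.na(idx)], collapse = ", "))
  if (length(idx) == 0) stop("design must contain at least one time point")
  subject <- list(regimen = profile$regimen, cov = cov,
                  times = profile$times, y = profile$concentrations)
  ctx <- .make_ctx(pop, subject)
  Oinv <- .omega_inv(pop)
  sd <- sqrt(pmax(pop$iiv, 1e-4))
  starts <- list(numeric(4))
  if (n_starts >= 2) starts <- c(starts, list(0.5 * sd))
  if (n_starts >= 3) starts <- c(starts, list(-0.5 * sd))
  fits <- lapply(starts, function(s)
    tryCatch(.map_fit(ctx, idx, Oinv, eta0 = s, maxit = 100),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    stop("MAP estimation failed for subject ", profile$subject_id,
         ": all starts errored")
  best <- fits[[which.min(vapply(fits, `[[`, 0, "objective"))]]
  if (!best$converged && best$iterations >= 100)
    warning("MAP optimiser hit the iteration cap for subject ",
            profile$subject_id)
  eta <- stats::setNames(best$eta, c("CL", "Q", "KA", "F"))
  typ <- typical_params(pop, cov)
  structure(list(eta = eta,
                 params = individual_params(typ, eta, pop$vc_slope),
                 fitted = .ctx_predict(ctx, best$eta, profile$times),
                 objective = best$objective, design = dtimes,
                 converged = best$converged),
            class = "map_result")
}

# ---- population fit ----------------------------------------------------

# Parameter transform table for the outer optimisation. Each row maps one
# scalar of the population model to one coordinate of the unconstrained
# vector: log for positive parameters, logit for F, atanh for the CL-Q
# correlation, identity for covariate coefficients and the Vc slope.
.build_partable <- function(model, any_po) {
  rows <- list()
  add <- function(name, value, trans) {
    rows[[length(rows) + 1]] <<- list(name = name, value = value,
                                      trans = trans)
  }
  th <- model$theta
  add("theta.CL", th$CL, "log")
  add("theta.Vc", th$Vc, "log")
  if (th$Q > 0) {
    add("theta.Q", th$Q, "log")
    add("theta.Vp", th$Vp, "log")
  }
  if (any_po) {
    add("theta.KA", th$KA, "log")
    if (th$ALAG > 0) add("theta.ALAG", th$ALAG, "log")
    add("theta.F", th$F, "logit")
  }
  for (i in seq_along(model$covariates)) {
    cf <- model$covariates[[i]]$coef
    for (j in seq_along(cf))
      add(sprintf("cov%d.%d", i, j), cf[j], "identity")
  }
  for (nm in names(model$iiv))
    if (model$iiv[nm] > 0) add(paste0("omega.", nm), model$iiv[nm], "log")
  if (model$corr_cl_q != 0 && model$iiv["CL"] > 0 && model$iiv["Q"] > 0)
    add("corr_cl_q", model$corr_cl_q, "atanh")
  if (model$vc_slope != 0) add("vc_slope", model$vc_slope, "identity")
  if (model$error$kind %in% c("additive", "combined") &&
      model$error$sigma_add > 0)
    add("sigma.add", model$error$sigma_add, "log")
  if (model$error$kind %in% c("proportional", "combined") &&
      model$error$sigma_prop > 0)
    add("sigma.prop", model$error$sigma_prop, "log")
  rows
}

.fwd <- function(value, trans) switch(trans,
  log = log(value), logit = stats::qlogis(value),
  atanh = atanh(value), identity = value)

.bwd <- function(x, trans) switch(trans,
  log = exp(x), logit = stats::plogis(x), atanh = tanh(x), identity = x)

.pack <- function(ptab) vapply(ptab, function(r) .fwd(r$value, r$trans), 0)

.unpack <- function(model, ptab, par) {
  for (i in seq_along(ptab)) {
    r <- ptab[[i]]
    val <- .bwd(par[i], r$trans)
    parts <- strsplit(r$name, ".", fixed = TRUE)[[1]]
    if (parts[1] == "theta") model$theta[[parts[2]]] <- val
    else if (parts[1] == "omega") model$iiv[parts[2]] <- val
    else if (parts[1] == "sigma") {
      if (parts[2] == "add") model$error$sigma_add <- val
      else model$error$sigma_prop <- val
    } else if (startsWith(parts[1], "cov")) {
      ti <- as.integer(sub("cov", "", parts[1]))
      tj <- as.integer(parts[2])
      model$covariates[[ti]]$coef[tj] <- val
    } else if (r$name == "corr_cl_q") model$corr_cl_q <- val
    else if (r$name == "vc_slope") model$vc_slope <- val
  }
  model
}

# Laplace -2 log marginal likelihood for one subject given its MAP fit.
.subject_ofv <- function(mfit, Oinv, logdet_omega) {
  Hhalf <- crossprod(mfit$J, mfit$J / mfit$v) + Oinv
  R <- tryCatch(chol(Hhalf), error = function(e)
    chol(Hhalf + diag(1e-8, 4)))
  mfit$objective + length(mfit$v) * log(2 * pi) + logdet_omega +
    2 * sum(log(diag(R)))
}

#' Fit a population model by Laplace-approximated marginal likelihood
#'
#' Nonlinear mixed-effects fit: the objective function value (OFV) is the sum
#' over subjects of the Laplace approximation to -2 log marginal likelihood,
#' computed around each subject's MAP random effects with a Gauss-Newton
#' Hessian. Fixed effects, covariate coefficients, random-effect standard
#' deviations, the CL-Q correlation, the Vc slope and residual-error SDs are
#' estimated on unconstrained transformed scales. KA, ALAG and F are held at
#' their starting values when the data contain no oral profiles (they are not
#' identifiable from IV data).
#'
#' @param dataset A `pk_dataset` (or NONMEM-style data.frame) with at least
#'   two subjects.
#' @param model A [population_model()] defining the structure to fit; its
#'   parameter values are the starting values.
#' @param init Optional named list (`theta`, `iiv`, `corr_cl_q`, `vc_slope`,
#'   `error`) overriding starting values.
#' @param compute_rse Compute relative standard errors from a numerical
#'   Hessian of the OFV (adds noticeable cost; default `FALSE`).
#' @param control List: `iter.max`, `eval.max`, `rel.tol` passed to the outer
#'   optimiser ([stats::nlminb()]).
#' @return Object of class `pop_fit`: `model` (fitted [population_model()]),
#'   `ofv`, `convergence` (optimiser diagnostics), `eta` (subjects x 4 MAP
#'   matrix), `ipred` list, `rse` (named RSE%, `NA` unless requested),
#'   `shrinkage` (eta shrinkage %, by effect), `n_subjects`, `n_obs`.
#' @export
fit_population <- function(dataset, model, init = NULL, compute_rse = FALSE,
                           control = list()) {
  stopifnot(inherits(model, "population_model"))
  subjects <- as_subjects(dataset)
  if (length(subjects) < 2) stop("population fit needs >= 2 subjects")
  if (!is.null(init)) {
    for (nm in names(init)) {
      if (nm == "theta") model$theta <- utils::modifyList(model$theta, init$theta)
      else if (nm == "iiv") model$iiv[names(init$iiv)] <- init$iiv
      else if (nm == "error") model$error <- init$error
      else model[[nm]] <- init[[nm]]
    }
  }
  any_po <- any(vapply(subjects, `[[`, "", "route") == "PO")
  ptab <- .build_partable(model, any_po)
  par0 <- .pack(ptab)
  n_obs <- sum(vapply(subjects, function(s) length(s$y), 0))

  # The inner MAP always starts from eta = 0 so the outer objective is a
  # deterministic, smooth function of the population parameters (a warm-start
  # cache would make it path-dependent and confuse the outer optimiser's
  # finite-difference gradients).
  objective <- function(par) {
    m <- .unpack(model, ptab, par)
    ofv <- tryCatch({
      om <- omega_matrix(m)
      diag(om) <- pmax(diag(om), 1e-8)
      Oinv <- solve(om)
      logdet_om <- determinant(om, logarithm = TRUE)$modulus[1]
      total <- 0
      for (i in seq_along(subjects)) {
        ctx <- .make_ctx(m, subjects[[i]])
        mf <- .map_fit(ctx, seq_along(ctx$times), Oinv, maxit = 100,
                       gtol = 1e-7)
        total <- total + .subject_ofv(mf, Oinv, logdet_om)
      }
      total
    }, error = function(e) {
      if (isTRUE(getOption("bayeslss.debug")))
        message("objective penalty: ", conditionMessage(e))
      NA_real_
    })
    if (!is.finite(ofv)) 1e10 else ofv
  }

  # Stage 1: cheap naive-pooled pre-fit (all random effects at zero) of the
  # fixed effects and error SDs, to start the marginal-likelihood stage close
  # to the data.
  # Only the disposition fixed effects: pooled sigma is inflated by IIV, and
  # pooled absorption parameters (KA/ALAG/F) are prone to spurious local
  # optima that the marginal stage then cannot leave.
  pooled_idx <- grep("^(theta\\.(CL|Vc|Q|Vp)$|cov)",
                     vapply(ptab, `[[`, "", "name"))
  if (isTRUE(control$pooled_init %||% TRUE) && length(pooled_idx)) {
    pooled_obj <- function(sub) {
      par <- par0
      par[pooled_idx] <- sub
      m <- .unpack(model, ptab, par)
      tryCatch({
        total <- 0
        for (s in subjects) {
          ctx <- .make_ctx(m, s)
          f <- .ctx_predict(ctx, numeric(4), ctx$times)
          v <- pmax(ctx$sp2 * f^2 + ctx$sa2, .V_FLOOR)
          total <- total + sum((ctx$y - f)^2 / v + log(v))
        }
        total
      }, error = function(e) 1e10)
    }
    p1 <- stats::nlminb(par0[pooled_idx], pooled_obj,
                        control = list(iter.max = 200, eval.max = 600))
    if (is.finite(p1$objective) && p1$objective < 1e10)
      par0[pooled_idx] <- p1$par
  }

  ctl <- utils::modifyList(list(iter.max = 200, eval.max = 800,
                                rel.tol = 1e-8), control)
  ctl$pooled_init <- NULL
  restarts <- ctl$restarts %||% 3
  ctl$restarts <- NULL
  # Residual-error SDs are bounded below at 1e-3 (ng/mL or fraction): exactly
  # noise-free data would otherwise drive log-sigma to -Inf.
  lower <- rep(-Inf, length(ptab))
  lower[grep("^sigma", vapply(ptab, `[[`, "", "name"))] <- log(1e-3)
  # Restart cycles: a quasi-Newton restart from the previous stopping point
  # rebuilds the curvature model and routinely escapes premature "false
  # convergence" stops on this objective.
  opt <- stats::nlminb(par0, objective, control = ctl, lower = lower)
  for (r in seq_len(restarts - 1)) {
    prev <- opt$objective
    opt2 <- stats::nlminb(opt$par, objective, control = ctl, lower = lower)
    if (opt2$objective <= prev) opt <- opt2
    if (prev - opt2$objective < 0.1) break
  }
  fitted_model <- .unpack(model, ptab, opt$par)

  # final per-subject MAP pass at the optimum
  om <- omega_matrix(fitted_model)
  diag(om) <- pmax(diag(om), 1e-8)
  Oinv <- solve(om)
  eta <- matrix(0, length(subjects), 4,
                dimnames = list(vapply(subjects, function(s) as.character(s$id), ""),
                                c("CL", "Q", "KA", "F")))
  ipred <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    ctx <- .make_ctx(fitted_model, subjects[[i]])
    mf <- .map_fit(ctx, seq_along(ctx$times), Oinv, maxit = 100, gtol = 1e-7)
    eta[i, ] <- mf$eta
    ipred[[i]] <- mf$f
  }
  sd_pop <- sqrt(pmax(diag(om), 0))
  sd_eta <- apply(eta, 2, stats::sd)
  shrink <- 100 * (1 - ifelse(sd_pop > 1e-6, sd_eta / sd_pop, NA))

  rse <- stats::setNames(rep(NA_real_, length(ptab)),
                         vapply(ptab, `[[`, "", "name"))
  if (compute_rse) {
    Hh <- tryCatch(stats::optimHess(opt$par, objective), error = function(e) NULL)
    if (!is.null(Hh)) {
      cv <- tryCatch(2 * solve(Hh), error = function(e) NULL)
      if (!is.null(cv)) {
        se_t <- sqrt(pmax(diag(cv), 0))
        for (i in seq_along(ptab)) {
          val <- .bwd(opt$par[i], ptab[[i]]$trans)
          # delta method back to the natural scale
          dnat <- switch(ptab[[i]]$trans,
                         log = val, logit = val * (1 - val),
                         atanh = 1 - val^2, identity = 1)
          rse[i] <- 100 * abs(se_t[i] * dnat / val)
        }
      }
    }
  }

  structure(list(model = fitted_model, ofv = opt$objective,
                 convergence = list(code = opt$convergence,
                                    message = opt$message,
                                    iterations = opt$iterations,
                                    evaluations = opt$evaluations),
                 eta = eta, ipred = ipred, rse = rse, shrinkage = shrink,
                 n_subjects = length(subjects), n_obs = n_obs,
                 partable = vapply(ptab, `[[`, "", "name")),
            class = "pop_fit")
}

#' @export
print.pop_fit <- function(x, ...) {
  cat(sprintf("Population fit: %d subjects, %d observations, OFV %.3f\n",
              x$n_subjects, x$n_obs, x$ofv))
  th <- unlist(x$model$theta)
  cat("  theta:", paste(sprintf("%s=%.4g", names(th), th), collapse = " "), "\n")
  cat("  IIV sd:", paste(sprintf("%s=%.3g", names(x$model$iiv), x$model$iiv),
                         collapse = " "), "\n")
  cat(sprintf("  error: add %.4g prop %.4g | convergence code %d\n",
              x$model$error$sigma_add, x$model$error$sigma_prop,
              x$convergence$code))
  invisible(x)
}

#' Likelihood-ratio comparison of nested fits
#'
#' Compares the OFV drop of a full model against the chi-square upper quantile
#' with `df` degrees of freedom at level `alpha` (e.g. 6.63 for df 1,
#' alpha 0.01; 7.87 for alpha 0.005).
#'
#' @param ofv_reduced,ofv_full OFVs of the nested (reduced) and full fits on
#'   the same data.
#' @param df Number of extra parameters in the full model.
#' @param alpha Significance level.
#' @return List: `delta` (OFV drop), `threshold`, `significant`, and
#'   `suspect_fit` (`TRUE` when the full model fits worse than the reduced one
#'   beyond tolerance, indicating an optimiser failure).
#' @export
lrt_compare <- function(ofv_reduced, ofv_full, df = 1, alpha = 0.01) {
  if (df < 1) stop("df must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  delta <- ofv_reduced - ofv_full
  threshold <- stats::qchisq(1 - alpha, df)
  list(delta = delta, threshold = threshold,
       significant = delta > threshold,
       suspect_fit = delta < -0.1)
}

#' Stepwise covariate model building
#'
#' Forward inclusion (most significant candidate added while any exceeds the
#' chi-square threshold at `alpha_forward`) followed by backward elimination
#' (terms whose removal raises the OFV by less than the `alpha_backward`
#' threshold are dropped). Candidates whose fits fail are skipped, not fatal.
#' Ties in the forward step are broken lexicographically by (parameter,
#' covariate) name.
#'
#' @param dataset A `pk_dataset`.
#' @param base_model Starting [population_model()] (typically with allometric
#'   weight scaling already in place).
#' @param candidates List of candidate [covariate_term()]s (their `coef` is
#'   the starting value for estimation, typically 0).
#' @param alpha_forward,alpha_backward Inclusion/retention levels (defaults
#'   0.01 and 0.005).
#' @param control Passed to [fit_population()].
#' @return List: `model` (final fitted model), `fit` (its `pop_fit`), `trail`
#'   (data.frame audit of every step: action, term, OFVs, delta, decision).
#' @export
covariate_search <- function(dataset, base_model, candidates,
                             alpha_forward = 0.01, alpha_backward = 0.005,
                             control = list()) {
  term_key <- function(tm) paste(tm$param, tm$covariate, sep = "~")
  trail <- list()
  log_step <- function(action, term, ofv_ref, ofv_new, delta, decision, note = "") {
    trail[[length(trail) + 1]] <<- data.frame(
      action = action, term = term, ofv_reference = ofv_ref,
      ofv_candidate = ofv_new, delta = delta, decision = decision,
      note = note, stringsAsFactors = FALSE)
  }
  current <- base_model
  fit_cur <- fit_population(dataset, current, control = control)
  if (!length(candidates))
    return(list(model = fit_cur$model, fit = fit_cur,
                trail = data.frame()))
  pool <- candidates[order(vapply(candidates, term_key, ""))]
  included <- list()

  repeat {  # forward inclusion
    best <- NULL
    for (cand in pool) {
      m_try <- tryCatch(
        population_model(current$theta, iiv = current$iiv,
                         corr_cl_q = current$corr_cl_q,
                         vc_slope = current$vc_slope, error = current$error,
                         covariates = c(current$covariates, list(cand)),
                         allometry = current$allometry),
        error = function(e) NULL)
      if (is.null(m_try)) next
      f_try <- tryCatch(fit_population(dataset, m_try, control = control),
                        error = function(e) NULL)
      if (is.null(f_try)) {
        log_step("forward", term_key(cand), fit_cur$ofv, NA, NA, "skipped",
                 "fit failed")
        next
      }
      df_cand <- length(cand$coef)
      lrt <- lrt_compare(fit_cur$ofv, f_try$ofv, df = df_cand,
                         alpha = alpha_forward)
      log_step("forward", term_key(cand), fit_cur$ofv, f_try$ofv, lrt$delta,
               if (lrt$significant) "significant" else "not significant")
      if (lrt$significant &&
          (is.null(best) || lrt$delta > best$delta + 1e-9))
        best <- list(cand = cand, fit = f_try, delta = lrt$delta)
    }
    if (is.null(best)) break
    included <- c(included, list(best$cand))
    pool <- pool[vapply(pool, term_key, "") != term_key(best$cand)]
    current <- best$fit$model
    fit_cur <- best$fit
    log_step("forward", term_key(best$cand), NA, fit_cur$ofv, best$delta,
             "included")
    if (!length(pool)) break
  }

  repeat {  # backward elimination
    if (!length(current$covariates)) break
    weakest <- NULL
    for (i in seq_along(current$covariates)) {
      tm <- current$covariates[[i]]
      m_red <- population_model(current$theta, iiv = current$iiv,
                                corr_cl_q = current$corr_cl_q,
                                vc_slope = current$vc_slope,
                                error = current$error,
                                covariates = current$covariates[-i],
                                allometry = current$allometry)
      f_red <- tryCatch(fit_population(dataset, m_red, control = control),
                        error = function(e) NULL)
      if (is.null(f_red)) {
        log_step("backward", term_key(tm), fit_cur$ofv, NA, NA, "kept",
                 "reduced fit failed")
        next
      }
      lrt <- lrt_compare(f_red$ofv, fit_cur$ofv, df = length(tm$coef),
                         alpha = alpha_backward)
      log_step("backward", term_key(tm), fit_cur$ofv, f_red$ofv, lrt$delta,
               if (lrt$significant) "kept" else "removable")
      if (!lrt$significant &&
          (is.null(weakest) || lrt$delta < weakest$delta))
        weakest <- list(i = i, fit = f_red, delta = lrt$delta)
    }
    if (is.null(weakest)) break
    log_step("backward", term_key(current$covariates[[weakest$i]]), NA,
             weakest$fit$ofv, weakest$delta, "removed")
    current <- weakest$fit$model
    fit_cur <- weakest$fit
  }

  list(model = fit_cur$model, fit = fit_cur,
       trail = do.call(rbind, trail))
}

#' Write a covariate-search audit trail to CSV
#'
#' @param search Result of [covariate_search()].
#' @param path Output CSV path.
#' @export
write_search_trail <- function(search, path) {
  utils::write.csv(search$trail, path, row.names = FALSE)
  invisible(path)
}
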