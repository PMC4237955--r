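# Analytic one-/two-compartment concentration engine.
#
# Unit conventions (fixed across the package): dose mg, volumes L, clearances
# L/h, times h. Internal concentrations are mg/L; everything exported to the
# user is ng/mL (1 mg/L = 1000 ng/mL), the scale clinical cyclosporine assays
# report on.

#' Structural pharmacokinetic parameters for one subject
#'
#' Container for the parameter vector of the two-compartment disposition model
#' with first-order absorption: clearance, central and peripheral volumes,
#' inter-compartmental clearance, absorption rate constant, absorption lag
#' time and oral bioavailability. Setting both `Q = 0` and `Vp = 0` collapses
#' the model to one compartment.
#'
#' @param CL Clearance, L/h. Strictly positive.
#' @param Vc Central volume of distribution, L. Strictly positive.
#' @param Q Inter-compartmental clearance, L/h. Non-negative; zero only
#'   together with `Vp = 0` (one-compartment model).
#' @param Vp Peripheral volume of distribution, L.
#' @param KA First-order absorption rate constant, 1/h. Required for oral
#'   dosing; may be `NA` for subjects only ever dosed intravenously.
#' @param ALAG Absorption lag time, h. Non-negative.
#' @param F Oral bioavailability, fraction in (0, 1].
#' @return An object of class `structural_params`.
#' @export
structural_params <- function(CL, Vc, Q = 0, Vp = 0, KA = NA_real_,
                              ALAG = 0, F = 1) {
  stopifnot(is.numeric(CL), is.numeric(Vc))
  if (!is.finite(CL) || CL <= 0) stop("CL must be finite and > 0")
  if (!is.finite(Vc) || Vc <= 0) stop("Vc must be finite and > 0")
  if (!is.finite(Q) || Q < 0) stop("Q must be finite and >= 0")
  if (!is.finite(Vp) || Vp < 0) stop("Vp must be finite and >= 0")
  if ((Q > 0) != (Vp > 0))
    stop("Q and Vp must both be positive (two-compartment) or both zero")
  if (!is.na(KA) && (!is.finite(KA) || KA <= 0)) stop("KA must be > 0 or NA")
  if (!is.finite(ALAG) || ALAG < 0) stop("ALAG must be >= 0")
  if (!is.finite(F) || F <= 0 || F > 1 + 1e-12)
    stop("F must be a fraction in (0, 1]")
  structure(list(CL = CL, Vc = Vc, Q = Q, Vp = Vp, KA = KA,
                 ALAG = ALAG, F = min(F, 1)),
            class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat("Structural PK parameters (", if (x$Q > 0) "two" else "one",
      "-compartment)\n", sep = "")
  cat(sprintf("  CL %.4g L/h  Vc %.4g L  Q %.4g L/h  Vp %.4g L\n",
              x$CL, x$Vc, x$Q, x$Vp))
  cat(sprintf("  KA %.4g 1/h  ALAG %.4g h  F %.4g\n", x$KA, x$ALAG, x$F))
  invisible(x)
}

#' Dosing regimen
#'
#' Describes repeated (BID by default) administration of a fixed dose:
#' intravenous zero-order infusion or oral first-order absorption.
#'
#' @param route `"IV"` (zero-order infusion) or `"PO"` (oral).
#' @param dose_amount Dose per administration, mg.
#' @param infusion_duration Infusion duration, h; IV only (default 2 h, the
#'   clinical protocol). Must be `NA` for oral dosing.
#' @param interval Inter-dose interval tau, h (default 12, twice daily).
#' @param steady_state Logical; profiles in this package are steady state
#'   unless stated otherwise.
#' @return An object of class `dosing_regimen`.
#' @export
dosing_regimen <- function(route = c("IV", "PO"), dose_amount,
                           infusion_duration = if (route[1] == "IV") 2 else NA_real_,
                           interval = 12, steady_state = TRUE) {
  route <- match.arg(route)
  if (!is.finite(dose_amount) || dose_amount <= 0)
    stop("dose_amount must be > 0")
  if (route == "IV") {
    if (!is.finite(infusion_duration) || infusion_duration <= 0)
      stop("IV dosing requires infusion_duration > 0")
  } else {
    if (!is.na(infusion_duration))
      stop("infusion_duration applies to IV dosing only; use NA for PO")
  }
  if (!is.finite(interval) || interval <= 0) stop("interval must be > 0")
  structure(list(route = route, dose_amount = dose_amount,
                 infusion_duration = infusion_duration,
                 interval = interval, steady_state = isTRUE(steady_state)),
            class = "dosing_regimen")
}

#' Concentration-time profile of one subject
#'
#' @param subject_id Opaque label.
#' @param times Sampling times, h post-dose, ascending, within `[0, interval]`.
#' @param concentrations Observed concentrations, ng/mL, non-negative.
#' @param regimen A [dosing_regimen()].
#' @return Object of class `concentration_profile`.
#' @export
concentration_profile <- function(subject_id, times, concentrations, regimen) {
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (length(times) != length(concentrations))
    stop("times and concentrations must have equal length")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly ascending")
  if (any(times < 0) || any(times > regimen$interval))
    stop("times must lie within [0, interval]")
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("concentrations must be finite and non-negative")
  structure(list(subject_id = subject_id, times = as.numeric(times),
                 concentrations = as.numeric(concentrations),
                 regimen = regimen),
            class = "concentration_profile")
}

# ---- disposition algebra -----------------------------------------------

# Eigenvalues (lambda) and unit-bolus macro coefficients (coef) of central
# disposition; C_bolus(t) = (D/Vc) * sum(coef * exp(-lambda t)), sum(coef)=1.
# Near-equal eigenvalues are separated by a 1e-8 relative perturbation to
# avoid the removable singularity in the bi-exponential coefficients.
.disposition <- function(CL, Vc, Q, Vp) {
  k10 <- CL / Vc
  if (Q <= 0 || Vp <= 0) return(list(lambda = k10, coef = 1))
  k12 <- Q / Vc
  k21 <- Q / Vp
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- s * s - 4 * p           # always >= 0 for real rate constants
  root <- sqrt(max(disc, 0))
  l1 <- (s + root) / 2
  l2 <- (s - root) / 2
  if (abs(l1 - l2) < 1e-10 * l1) {
    l1 <- l1 * (1 + 1e-8)
    l2 <- l2 * (1 - 1e-8)
  }
  c1 <- (l1 - k21) / (l1 - l2)
  c2 <- (k21 - l2) / (l1 - l2)
  list(lambda = c(l1, l2), coef = c(c1, c2))
}

# Absorption rate constant nudged off disposition eigenvalues (removable
# singularity in the oral closed form).
.ka_safe <- function(ka, lambda) {
  while (any(abs(ka - lambda) < 1e-8 * ka)) ka <- ka * (1 + 1e-8)
  ka
}

# Single-dose central concentration in mg/L, vectorised over t (h since this
# dose). Closed forms; t < 0 contributes 0.
.conc_single <- function(params, regimen, t) {
  dsp <- .disposition(params$CL, params$Vc, params$Q, params$Vp)
  lam <- dsp$lambda
  cf <- dsp$coef
  out <- numeric(length(t))
  if (regimen$route == "IV") {
    Tinf <- regimen$infusion_duration
    R <- regimen$dose_amount / Tinf      # mg/h
    during <- t >= 0 & t <= Tinf
    after <- t > Tinf
    if (any(during)) {
      td <- t[during]
      acc <- 0
      for (i in seq_along(lam))
        acc <- acc + cf[i] / lam[i] * (-expm1(-lam[i] * td))
      out[during] <- R / params$Vc * acc
    }
    if (any(after)) {
      ta <- t[after]
      acc <- 0
      for (i in seq_along(lam))
        acc <- acc + cf[i] / lam[i] * (-expm1(-lam[i] * Tinf)) *
          exp(-lam[i] * (ta - Tinf))
      out[after] <- R / params$Vc * acc
    }
  } else {
    if (is.na(params$KA)) stop("oral dosing requires KA")
    ka <- .ka_safe(params$KA, lam)
    s <- t - params$ALAG
    pos <- s > 0
    if (any(pos)) {
      sp <- s[pos]
      amt <- params$F * regimen$dose_amount
      acc <- 0
      for (i in seq_along(lam))
        acc <- acc + cf[i] / (ka - lam[i]) *
          (exp(-lam[i] * sp) - exp(-ka * sp))
      out[pos] <- amt * ka / params$Vc * acc
    }
  }
  if (any(!is.finite(out)))
    stop("non-finite concentration (degenerate disposition eigenvalues?); ",
         "check CL/Vc/Q/Vp/KA")
  out
}

# Exponential tail representation: for t >= tail_start the single-dose curve
# equals sum(coef * exp(-rate * t)) exactly. Used for closed-form steady-state
# accumulation.
.tail_terms <- function(params, regimen) {
  dsp <- .disposition(params$CL, params$Vc, params$Q, params$Vp)
  lam <- dsp$lambda
  cf <- dsp$coef
  if (regimen$route == "IV") {
    Tinf <- regimen$infusion_duration
    R <- regimen$dose_amount / Tinf
    coef <- R / params$Vc * cf / lam * (exp(lam * Tinf) - 1)
    list(rate = lam, coef = coef, tail_start = Tinf)
  } else {
    ka <- .ka_safe(params$KA, lam)
    a <- params$ALAG
    amt <- params$F * regimen$dose_amount
    k0 <- amt * ka / params$Vc
    coef <- c(k0 * cf / (ka - lam) * exp(lam * a),
              -k0 * sum(cf / (ka - lam)) * exp(ka * a))
    list(rate = c(lam, ka), coef = coef, tail_start = a)
  }
}

# Steady-state concentration in mg/L at t within [0, tau]: current-dose
# contribution plus the geometric sum of all earlier doses' exponential tails
# (valid because tail_start < tau for every regimen used here).
.conc_ss <- function(params, regimen, t) {
  tau <- regimen$interval
  tt <- .tail_terms(params, regimen)
  if (tt$tail_start >= tau)
    stop("steady-state accumulation requires lag/infusion to end within one interval")
  out <- .conc_single(params, regimen, t)
  for (i in seq_along(tt$rate)) {
    r <- tt$rate[i]
    g <- exp(-r * tau) / (-expm1(-r * tau))   # sum_{n>=1} exp(-r n tau)
    out <- out + tt$coef[i] * exp(-r * t) * g
  }
  if (any(!is.finite(out)))
    stop("non-finite steady-state concentration; check parameters")
  out
}

#' Concentration after a single dose
#'
#' Analytic central-compartment concentration following one administration.
#' Oral doses enter by first-order absorption delayed by the lag time and
#' scaled by bioavailability; intravenous doses by zero-order infusion.
#'
#' @param params A [structural_params()] object.
#' @param regimen A [dosing_regimen()] object.
#' @param t Time(s) since the dose, h; non-negative.
#' @return Concentration(s) in ng/mL.
#' @export
single_dose_concentration <- function(params, regimen, t) {
  stopifnot(inherits(params, "structural_params"),
            inherits(regimen, "dosing_regimen"))
  if (any(t < 0)) stop("t must be >= 0")
  1000 * .conc_single(params, regimen, t)
}

#' Concentration at steady state under repeated dosing
#'
#' Concentration within one inter-dose interval at steady state, i.e. after
#' full accumulation of the repeated regimen, so that `C(0) = C(interval)`.
#' Accumulation uses the closed-form geometric sum of the exponential dose
#' tails, which equals the infinite superposition of past doses.
#'
#' @inheritParams single_dose_concentration
#' @param t Time(s) within the monitored interval, h, in `[0, interval]`.
#' @return Concentration(s) in ng/mL.
#' @export
steady_state_concentration <- function(params, regimen, t) {
  stopifnot(inherits(params, "structural_params"),
            inherits(regimen, "dosing_regimen"))
  if (any(t < 0) || any(t > regimen$interval))
    stop("t must lie within [0, interval]")
  1000 * .conc_ss(params, regimen, t)
}

#' Linear trapezoidal AUC
#'
#' Area under the concentration-time curve over the supplied grid by the
#' linear trapezoidal method; with a grid spanning 0-12 h this is the AUC0-12
#' used for cyclosporine exposure monitoring.
#'
#' @param times Ascending sampling times, h (at least two).
#' @param concentrations Concentrations at `times`, ng/mL.
#' @return AUC in ng.h/mL.
#' @export
trapezoidal_auc <- function(times, concentrations) {
  if (length(times) != length(concentrations))
    stop("times and concentrations must have equal length")
  if (length(times) < 2) stop("need at least two points")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly ascending")
  dt <- diff(times)
  sum(dt * (concentrations[-1] + concentrations[-length(concentrations)]) / 2)
}

#' Nominal sampling grids of the clinical protocol
#'
#' Nine sampling times per route: pre-dose plus 2, 2.5, 3, 4, 6, 8, 10, 12 h
#' for intravenous profiles and pre-dose plus 0.5, 1, 1.5, 2, 3, 4, 8, 12 h
#' for oral profiles.
#'
#' @param route `"IV"` or `"PO"`.
#' @return Numeric vector of 9 times, h.
#' @export
nominal_grid <- function(route = c("IV", "PO")) {
  route <- match.arg(route)
  if (route == "IV") c(0, 2, 2.5, 3, 4, 6, 8, 10, 12)
  else c(0, 0.5, 1, 1.5, 2, 3, 4, 8, 12)
}
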