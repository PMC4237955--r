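# Virtual pediatric cohort generator. The study's raw patient data are not
# public, so analyses are exercised on simulated cohorts with the same
# statistical structure: steady-state BID profiles on the nominal 9-point
# sampling grids, covariates spanning the published cohort ranges, exponential
# IIV with correlated CL-Q effects, combined/additive residual error, and the
# assay's 30 ng/mL quantification and 1500 ng/mL dilution limits.

#' Cohort specification
#'
#' Defines the size and generating conditions of a simulated cohort. Defaults
#' reproduce the published study conditions: 23 IV + 39 PO profiles, median
#' doses 2.5 (IV) and 4.2 (PO) mg/kg/day split twice daily, covariates within
#' the published ranges.
#'
#' @param n_iv_profiles,n_po_profiles Number of IV / PO profiles (>= 1; either
#'   may be 0 if the other is positive).
#' @param seed Mandatory integer seed; the generator is fully reproducible.
#' @param dose_iv,dose_po Daily dose, mg/kg/day, split into two doses.
#' @param grid_iv,grid_po Sampling grids, h within [0, 12].
#' @param ranges_iv,ranges_po Covariate ranges, each a list with two-element
#'   `WT` (kg), `AG` (years), `TPT` (months), `AP` (U/L) entries.
#' @param lloq,uloq Assay lower/upper quantification limits, ng/mL.
#' @param bql `"flag"` (default: retain below-quantification values, flagged)
#'   or `"drop"` (remove them; profiles keep >= 7 points or are excluded).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_iv_profiles = 23, n_po_profiles = 39, seed,
                        dose_iv = 2.5, dose_po = 4.2,
                        grid_iv = nominal_grid("IV"),
                        grid_po = nominal_grid("PO"),
                        ranges_iv = list(WT = c(10, 81), AG = c(1, 17.9),
                                         TPT = c(0.1, 1.7), AP = c(1.9, 203)),
                        ranges_po = list(WT = c(8, 83), AG = c(1.2, 18.3),
                                         TPT = c(0.7, 9.1), AP = c(53, 302)),
                        lloq = 30, uloq = 1500, bql = c("flag", "drop")) {
  if (missing(seed) || !is.finite(seed)) stop("seed is mandatory")
  bql <- match.arg(bql)
  if (n_iv_profiles < 0 || n_po_profiles < 0 ||
      n_iv_profiles + n_po_profiles < 1)
    stop("need at least one profile")
  for (g in list(grid_iv, grid_po))
    if (any(g < 0) || any(g > 12) || is.unsorted(g, strictly = TRUE))
      stop("grids must be ascending within [0, 12]")
  chk <- function(r) {
    for (nm in c("WT", "AG", "TPT", "AP")) {
      v <- r[[nm]]
      if (length(v) != 2 || any(!is.finite(v)) || v[2] < v[1])
        stop("malformed covariate range for ", nm)
    }
  }
  chk(ranges_iv); chk(ranges_po)
  structure(list(n_iv_profiles = n_iv_profiles,
                 n_po_profiles = n_po_profiles, seed = as.integer(seed),
                 dose_iv = dose_iv, dose_po = dose_po,
                 grid_iv = grid_iv, grid_po = grid_po,
                 ranges_iv = ranges_iv, ranges_po = ranges_po,
                 lloq = lloq, uloq = uloq, bql = bql),
            class = "cohort_spec")
}

# Pediatric weight-for-age growth curve used to couple WT and AG:
# median weight ~ 10 * AG^0.647 kg (10 kg at 1 y, ~65 kg at 18 y).
.growth_age_from_wt <- function(WT) (WT / 10)^(1 / 0.647)

#' Sample one subject's covariates
#'
#' Weight is log-uniform within the route's published range; age is derived
#' from weight through an inverted pediatric growth curve with log-normal
#' noise (so the two are positively coupled), clamped to the published range;
#' time post transplantation and alkaline phosphatase are uniform within their
#' ranges. Dosage form is `"IV"` for IV subjects and suspension/capsule with
#' the published 19/20 split for oral subjects. Uses R's global RNG.
#'
#' @param spec A [cohort_spec()].
#' @param route `"IV"` or `"PO"`.
#' @return A [covariate_vector()].
#' @export
sample_covariates <- function(spec, route = c("IV", "PO")) {
  route <- match.arg(route)
  r <- if (route == "IV") spec$ranges_iv else spec$ranges_po
  runif1 <- function(v) if (v[1] == v[2]) v[1] else stats::runif(1, v[1], v[2])
  WT <- exp(if (r$WT[1] == r$WT[2]) log(r$WT[1]) else
            stats::runif(1, log(r$WT[1]), log(r$WT[2])))
  AG <- .growth_age_from_wt(WT) * exp(stats::rnorm(1, 0, 0.15))
  AG <- min(max(AG, r$AG[1]), r$AG[2])
  covariate_vector(
    WT = WT, AG = AG, TPT = runif1(r$TPT), AP = runif1(r$AP),
    FORM = if (route == "IV") "IV" else
      sample(c("suspension", "capsule"), 1, prob = c(19, 20)),
    SEX = sample(c("M", "F"), 1))
}

#' Sample between-subject random effects
#'
#' Draws `n` multivariate-normal random-effect vectors (`eta_CL`, `eta_Q`,
#' `eta_KA`, `eta_F`) with mean zero and the model's expanded omega
#' covariance. Uses R's global RNG.
#'
#' @param pop A [population_model()].
#' @param n Number of draws.
#' @return `n` x 4 matrix with columns CL, Q, KA, F.
#' @export
sample_random_effects <- function(pop, n = 1) {
  om <- omega_matrix(pop)  # raises if not PSD
  ev <- eigen(om, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 4)
  z <- matrix(stats::rnorm(4 * n), nrow = 4)
  eta <- t(L %*% z)
  colnames(eta) <- colnames(om)
  eta
}

#' Simulate one steady-state profile
#'
#' Computes the subject's noise-free (IPRED-truth) steady-state concentrations
#' on the grid and overlays residual error: `obs = ipred*(1+eps1) + eps2`,
#' floored at zero. Values below the lower quantification limit are flagged
#' `bql`; values above the dilution limit are flagged `diluted`; both are
#' retained. Uses R's global RNG for the residual draws.
#'
#' @param pop Generating [population_model()].
#' @param cov Subject [covariate_vector()].
#' @param regimen Subject [dosing_regimen()].
#' @param grid Sampling times, h, within one interval.
#' @param eta Named random-effect vector (see [sample_random_effects()]).
#' @param lloq,uloq Quantification/dilution limits, ng/mL.
#' @return List with `ipred`, `obs`, `eps1`, `eps2`, `bql`, `diluted`,
#'   `params` (the subject's true [structural_params()]) and inputs.
#' @export
simulate_profile <- function(pop, cov, regimen, grid, eta,
                             lloq = 30, uloq = 1500) {
  typ <- typical_params(pop, cov)
  ind <- individual_params(typ, eta, vc_slope = pop$vc_slope)
  ipred <- steady_state_concentration(ind, regimen, grid)
  n <- length(grid)
  err <- pop$error
  eps1 <- stats::rnorm(n, 0, err$sigma_prop)
  eps2 <- stats::rnorm(n, 0, err$sigma_add)
  obs <- pmax(ipred * (1 + eps1) + eps2, 0)
  list(times = grid, ipred = ipred, obs = obs, eps1 = eps1, eps2 = eps2,
       bql = obs < lloq, diluted = obs > uloq, params = ind, eta = eta,
       cov = cov, regimen = regimen)
}

#' Generate a simulated cohort dataset
#'
#' Reproducibly simulates the cohort described by `spec` under the supplied
#' generating model(s) and returns a NONMEM-style rectangular dataset together
#' with a ground-truth sidecar from which every observed value can be replayed
#' exactly.
#'
#' @param spec A [cohort_spec()].
#' @param model Generating model: a single [population_model()] used for both
#'   routes, or `list(IV = ..., PO = ...)`. Default: the published structural
#'   model with combined error for IV profiles and additive error for PO
#'   profiles (the best-performing pair).
#' @return Object of class `pk_dataset`: list with `data` (columns ID, TIME,
#'   AMT, RATE, EVID, MDV, DV, CMT, BQL, DIL, WT, AG, TPT, AP, FORM, SEX;
#'   dose records EVID = 1, observations EVID = 0), `truth` (one row per
#'   observation: true parameters, random effects, noise-free concentration
#'   and residual draws), and `spec`.
#' @export
generate_dataset <- function(spec, model = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(model))
    model <- list(IV = csa_structural_model("combined"),
                  PO = csa_structural_model("additive"))
  if (inherits(model, "population_model"))
    model <- list(IV = model, PO = model)
  stopifnot(inherits(model$IV, "population_model"),
            inherits(model$PO, "population_model"))
  set.seed(spec$seed)
  routes <- c(rep("IV", spec$n_iv_profiles), rep("PO", spec$n_po_profiles))
  rows <- list()
  truth <- list()
  for (i in seq_along(routes)) {
    route <- routes[i]
    pop <- model[[route]]
    grid <- if (route == "IV") spec$grid_iv else spec$grid_po
    cov <- sample_covariates(spec, route)
    daily <- if (route == "IV") spec$dose_iv else spec$dose_po
    dose <- max(round(daily * cov$WT / 2), 1)
    regimen <- dosing_regimen(route, dose_amount = dose,
                              infusion_duration = if (route == "IV") 2 else NA_real_)
    eta <- drop(sample_random_effects(pop, 1))
    prof <- simulate_profile(pop, cov, regimen, grid, eta,
                             lloq = spec$lloq, uloq = spec$uloq)
    keep <- rep(TRUE, length(grid))
    if (spec$bql == "drop") keep <- !prof$bql
    if (sum(keep) < 7) next  # inclusion rule: >= 7 concentration records
    base <- data.frame(ID = i, WT = cov$WT, AG = cov$AG, TPT = cov$TPT,
                       AP = cov$AP, FORM = cov$FORM, SEX = cov$SEX,
                       stringsAsFactors = FALSE)
    dose_row <- cbind(data.frame(
      TIME = 0, AMT = dose,
      RATE = if (route == "IV") dose / regimen$infusion_duration else 0,
      EVID = 1, MDV = 1, DV = NA_real_,
      CMT = if (route == "IV") 2L else 1L), base)
    obs_rows <- cbind(data.frame(
      TIME = grid[keep], AMT = 0, RATE = 0, EVID = 0, MDV = 0,
      DV = round(prof$obs[keep], 6), CMT = 2L), base)
    dr <- rbind(dose_row, obs_rows)
    dr$BQL <- c(FALSE, prof$bql[keep])
    dr$DIL <- c(FALSE, prof$diluted[keep])
    rows[[length(rows) + 1]] <- dr
    p <- prof$params
    truth[[length(truth) + 1]] <- data.frame(
      ID = i, TIME = grid[keep], ROUTE = route, DOSE = dose,
      IPRED_TRUE = prof$ipred[keep], EPS1 = prof$eps1[keep],
      EPS2 = prof$eps2[keep], DV = round(prof$obs[keep], 6),
      CL = p$CL, VC = p$Vc, Q = p$Q, VP = p$Vp, KA = p$KA,
      ALAG = p$ALAG, F = p$F,
      ETA_CL = eta["CL"], ETA_Q = eta["Q"], ETA_KA = eta["KA"],
      ETA_F = eta["F"], row.names = NULL)
  }
  data <- do.call(rbind, rows)
  cols <- c("ID", "TIME", "AMT", "RATE", "EVID", "MDV", "DV", "CMT",
            "BQL", "DIL", "WT", "AG", "TPT", "AP", "FORM", "SEX")
  data <- data[, cols]
  rownames(data) <- NULL
  structure(list(data = data, truth = do.call(rbind, truth), spec = spec),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  n_obs <- sum(x$data$EVID == 0)
  ids <- unique(x$data$ID)
  cat(sprintf("Simulated PK dataset: %d profiles, %d observations\n",
              length(ids), n_obs))
  invisible(x)
}

#' Write / read a simulated dataset as CSV
#'
#' `write_pk_dataset()` writes the NONMEM-style dataset and its ground-truth
#' sidecar (`<stem>.csv`, `<stem>_truth.csv`); `read_pk_dataset()` restores
#' them.
#'
#' @param ds A `pk_dataset`.
#' @param stem Path stem (without extension).
#' @return The stem (write) or a `pk_dataset` without spec (read).
#' @export
write_pk_dataset <- function(ds, stem) {
  stopifnot(inherits(ds, "pk_dataset"))
  utils::write.csv(ds$data, paste0(stem, ".csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(ds$truth, paste0(stem, "_truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(stem)
}

#' @rdname write_pk_dataset
#' @export
read_pk_dataset <- function(stem) {
  data <- utils::read.csv(paste0(stem, ".csv"), stringsAsFactors = FALSE)
  tfile <- paste0(stem, "_truth.csv")
  truth <- if (file.exists(tfile)) utils::read.csv(tfile) else NULL
  structure(list(data = data, truth = truth, spec = NULL),
            class = "pk_dataset")
}

# Normalise a pk_dataset (or bare NONMEM-style data.frame) into a per-subject
# list used by the estimation and LSS layers: id, route, regimen, cov, times,
# y, profile.
as_subjects <- function(dataset) {
  data <- if (inherits(dataset, "pk_dataset")) dataset$data else dataset
  stopifnot(all(c("ID", "TIME", "AMT", "EVID", "DV") %in% names(data)))
  out <- list()
  for (id in unique(data$ID)) {
    d <- data[data$ID == id, ]
    dose_row <- d[d$EVID == 1, ][1, ]
    obs <- d[d$EVID == 0, ]
    obs <- obs[order(obs$TIME), ]
    route <- if (!is.null(dose_row$RATE) && isTRUE(dose_row$RATE > 0))
      "IV" else "PO"
    regimen <- dosing_regimen(
      route, dose_amount = dose_row$AMT,
      infusion_duration = if (route == "IV") dose_row$AMT / dose_row$RATE
                          else NA_real_)
    cov <- covariate_vector(
      WT = dose_row$WT, AG = dose_row$AG,
      TPT = if (is.null(dose_row$TPT)) 0 else dose_row$TPT,
      AP = if (is.null(dose_row$AP)) 100 else dose_row$AP,
      FORM = if (is.null(dose_row$FORM)) route else dose_row$FORM,
      SEX = if (is.null(dose_row$SEX)) "M" else dose_row$SEX)
    profile <- concentration_profile(id, obs$TIME, obs$DV, regimen)
    out[[length(out) + 1]] <- list(id = id, route = route, regimen = regimen,
                                   cov = cov, times = obs$TIME, y = obs$DV,
                                   profile = profile)
  }
  out
}
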