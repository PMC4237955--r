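# Limited-sampling-strategy engine: exhaustive design enumeration, MAP-based
# AUC prediction, leave-one-out cross-validated evaluation, error indices and
# representative-design selection.
#
# A design is a subset (1-4 points) of the nominal 9-point sampling grid. Its
# cross-validated prediction error for profile i compares the AUC predicted
# from the design's concentrations (via MAP estimation under a population
# model fitted without profile i) against a reference AUC: the observed AUC
# (trapezoid on measured concentrations) or the "underlying" AUC (trapezoid on
# the model's individual predictions with residual error excluded).

#' Limited sampling design
#'
#' @param times Subset of the nominal grid, 1-4 unique times (h).
#' @param route Optional route tag (`"IV"`/`"PO"`).
#' @return Object of class `lss_design`.
#' @export
lss_design <- function(times, route = NA_character_) {
  times <- sort(as.numeric(times))
  if (length(times) < 1 || length(times) > 4)
    stop("a design holds 1 to 4 time points")
  if (anyDuplicated(times)) stop("design times must be unique")
  structure(list(times = times, route = route,
                 label = paste0("C", times, collapse = ", ")),
            class = "lss_design")
}

#' @export
print.lss_design <- function(x, ...) {
  cat("LSS design:", x$label,
      if (!is.na(x$route)) paste0(" (", x$route, ")"), "\n")
  invisible(x)
}

#' Enumerate all limited sampling designs over a grid
#'
#' All subsets of 1 to `max_points` sampling times, ordered by size and then
#' lexicographically by time; a 9-point grid with `max_points = 4` yields
#' 9 + 36 + 84 + 126 = 255 designs.
#'
#' @param grid Sampling grid (distinct times, h).
#' @param max_points Largest design size (default 4).
#' @param route Optional route tag copied onto every design.
#' @return List of [lss_design()] objects.
#' @export
enumerate_lss <- function(grid, max_points = 4, route = NA_character_) {
  grid <- as.numeric(grid)
  if (anyDuplicated(grid)) stop("grid contains duplicate times")
  grid <- sort(grid)
  max_points <- min(max_points, length(grid))
  out <- list()
  for (k in seq_len(max_points)) {
    sets <- utils::combn(grid, k, simplify = FALSE)
    out <- c(out, lapply(sets, lss_design, route = route))
  }
  out
}

#' Predict the full-interval AUC from a limited design
#'
#' MAP-estimates the subject's random effects from the design's
#' concentrations only, predicts the full sampling grid from the resulting
#' individual parameters, and integrates it by the trapezoidal method.
#'
#' @param pop A [population_model()].
#' @param profile A [concentration_profile()] containing the design's times.
#' @param cov The subject's [covariate_vector()].
#' @param design An [lss_design()] (or numeric times).
#' @return List: `auc` (ng.h/mL), `map` (the [map_estimate()] result).
#' @export
predict_auc <- function(pop, profile, cov, design) {
  mp <- map_estimate(pop, profile, cov, design = design)
  list(auc = trapezoidal_auc(profile$times, mp$fitted), map = mp)
}

#' Underlying (residual-error-free) AUC of a profile
#'
#' MAP-estimates the subject's random effects from all available
#' concentrations and integrates the individual predicted (IPRED) curve: an
#' AUC that excludes residual error and so reflects the intrinsic exposure
#' better than the observed trapezoid when measurements are noisy.
#'
#' @inheritParams predict_auc
#' @return AUC in ng.h/mL.
#' @export
underlying_auc <- function(pop, profile, cov) {
  mp <- map_estimate(pop, profile, cov, design = NULL)
  trapezoidal_auc(profile$times, mp$fitted)
}

# Evaluate expr with a private RNG stream, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Prediction-error indices for one design
#'
#' Given per-profile relative prediction errors `E_i% = 100 (AUCpred_i -
#' AUCref_i)/AUCref_i`, computes the mean relative error ME%, the root mean
#' squared relative error RMSE%, the 95th percentile of |E_i|% (95th PAE%,
#' linear interpolation between order statistics), error-category counts
#' (E% < -20, within +/-20, > +20), seeded percentile-bootstrap confidence
#' intervals for ME% and RMSE%, and symmetry diagnostics (min, max, moment
#' skewness) since relative errors can mislead on highly asymmetric data.
#'
#' @param E Numeric vector of relative errors, percent (N >= 1).
#' @param n_boot Bootstrap resamples for the CIs (default 2000).
#' @param boot_seed Seed for the bootstrap stream (does not disturb the
#'   caller's RNG).
#' @param conf Confidence level (default 0.95).
#' @return List with `n`, `me`, `rmse`, `pae95`, `me_ci`, `rmse_ci`,
#'   `categories` (named counts summing to N), `min`, `max`, `skewness`.
#' @export
error_indices <- function(E, n_boot = 2000, boot_seed = 1, conf = 0.95) {
  E <- as.numeric(E)
  if (!length(E)) stop("E must contain at least one error")
  if (any(!is.finite(E))) stop("E contains non-finite values")
  n <- length(E)
  me <- mean(E)
  rmse <- sqrt(mean(E^2))
  pae95 <- unname(stats::quantile(abs(E), 0.95, type = 7))
  cats <- c(below = sum(E < -20), within = sum(E >= -20 & E <= 20),
            above = sum(E > 20))
  a <- (1 - conf) / 2
  cis <- .with_seed(boot_seed, {
    bm <- br <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      Eb <- E[sample.int(n, n, replace = TRUE)]
      bm[b] <- mean(Eb)
      br[b] <- sqrt(mean(Eb^2))
    }
    list(me = unname(stats::quantile(bm, c(a, 1 - a))),
         rmse = unname(stats::quantile(br, c(a, 1 - a))))
  })
  m2 <- mean((E - me)^2)
  skew <- if (n >= 3 && m2 > 0) mean((E - me)^3) / m2^1.5 else NA_real_
  list(n = n, me = me, rmse = rmse, pae95 = pae95,
       me_ci = cis$me, rmse_ci = cis$rmse, categories = cats,
       min = min(E), max = max(E), skewness = skew)
}

#' Leave-one-out cross-validated evaluation of limited sampling designs
#'
#' For each profile i: the population model is fitted to all other profiles
#' (`refit = TRUE`, the full procedure, warm-started from the full-data fit;
#' `refit = FALSE` reuses the full-data fit for every fold — a fast,
#' documented approximation), the left-out profile's AUC is predicted from
#' each design via MAP, and relative errors against the reference AUC are
#' aggregated into error indices.
#'
#' @param dataset A `pk_dataset` (or NONMEM-style data.frame) with >= 3
#'   profiles.
#' @param model [population_model()] structure/starting values.
#' @param designs One [lss_design()] or a list of them (evaluated in a single
#'   cross-validation pass).
#' @param refit Refit the population model per fold (default `TRUE`).
#' @param target `"observed"` (trapezoid on measured concentrations) or
#'   `"underlying"` (trapezoid on the fold model's IPRED from the full grid).
#' @param route Optional filter: evaluate only profiles of this route.
#' @param fitted Optional precomputed full-data `pop_fit` to reuse.
#' @param fit_control Control list for the fold fits (see
#'   [fit_population()]).
#' @param n_boot,boot_seed Bootstrap settings for [error_indices()].
#' @return A single `lss_evaluation` (list with the design, target, E vector
#'   and all indices) or a list of them, in `designs` order. Evaluations are
#'   marked `partial` when more than 10% of folds failed.
#' @export
loocv_evaluate <- function(dataset, model, designs, refit = TRUE,
                           target = c("observed", "underlying"),
                           route = NULL, fitted = NULL,
                           fit_control = list(), n_boot = 2000,
                           boot_seed = 1) {
  target <- match.arg(target)
  single <- inherits(designs, "lss_design")
  if (single) designs <- list(designs)
  subjects <- as_subjects(dataset)
  if (!is.null(route))
    subjects <- Filter(function(s) s$route == route, subjects)
  N <- length(subjects)
  if (N < 3) stop("cross-validation needs at least 3 profiles")
  if (is.null(fitted))
    fitted <- fit_population(dataset, model, control = fit_control)
  stopifnot(inherits(fitted, "pop_fit"))
  full_model <- fitted$model

  all_subjects <- as_subjects(dataset)
  E <- matrix(NA_real_, N, length(designs))
  failed <- character()
  for (i in seq_len(N)) {
    s <- subjects[[i]]
    res <- tryCatch({
      pop_i <- if (refit) {
        rest <- Filter(function(x) !identical(x$id, s$id), all_subjects)
        rest_data <- if (inherits(dataset, "pk_dataset")) {
          d <- dataset$data
          d[d$ID != s$id, ]
        } else dataset[dataset$ID != s$id, ]
        fit_population(rest_data, full_model, control = fit_control)$model
      } else full_model
      ref <- if (target == "observed") trapezoidal_auc(s$times, s$y)
             else underlying_auc(pop_i, s$profile, s$cov)
      vapply(designs, function(d) {
        pr <- predict_auc(pop_i, s$profile, s$cov, d)
        100 * (pr$auc - ref) / ref
      }, 0)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("profile %s: %s", s$id, conditionMessage(res)))
    } else {
      E[i, ] <- res
    }
  }
  partial <- length(failed) > 0.1 * N
  out <- lapply(seq_along(designs), function(j) {
    Ej <- E[, j]
    Ej <- Ej[is.finite(Ej)]
    idx <- error_indices(Ej, n_boot = n_boot, boot_seed = boot_seed)
    structure(c(list(design = designs[[j]], label = designs[[j]]$label,
                     size = length(designs[[j]]$times), target = target,
                     E = Ej, partial = partial, failed_folds = failed),
                idx),
              class = "lss_evaluation")
  })
  if (single) out[[1]] else out
}

#' @export
print.lss_evaluation <- function(x, ...) {
  cat(sprintf("LSS %s [%s AUC, N=%d]: 95th PAE%% %.2f | RMSE%% %.2f (%.2f, %.2f) | ME%% %.2f (%.2f, %.2f)\n",
              x$label, x$target, x$n, x$pae95, x$rmse, x$rmse_ci[1],
              x$rmse_ci[2], x$me, x$me_ci[1], x$me_ci[2]))
  invisible(x)
}

#' Tabulate a list of design evaluations
#'
#' @param evals List of `lss_evaluation` objects.
#' @return data.frame with one row per design: label, size, whether C0 is
#'   included, latest sampling time, and the error indices.
#' @export
evaluation_table <- function(evals) {
  if (inherits(evals, "lss_evaluation")) evals <- list(evals)
  do.call(rbind, lapply(evals, function(e) data.frame(
    design = e$label, size = e$size,
    includes_c0 = 0 %in% e$design$times,
    tmax = max(e$design$times),
    n = e$n, pae95 = e$pae95, rmse = e$rmse, me = e$me,
    n_below = unname(e$categories["below"]),
    n_within = unname(e$categories["within"]),
    n_above = unname(e$categories["above"]),
    target = e$target, stringsAsFactors = FALSE)))
}

#' Select representative designs per size subgroup
#'
#' Mirrors the published shortlist logic: within each design-size subgroup
#' (1-4 points), pick (a) the globally best design by 95th PAE% and (b-d) the
#' best three among clinically practical designs — those including the
#' pre-dose sample C0 with no sample later than `window_hours` post-dose —
#' then de-duplicate. Ties break by lower RMSE%, then earlier last sample,
#' then label. The one-point subgroup typically contributes only two rows
#' (the best single point and C0 itself).
#'
#' @param evals List of `lss_evaluation`s (or an [evaluation_table()]
#'   data.frame) covering the sizes to shortlist.
#' @param window_hours Clinical sampling window for the restricted picks
#'   (default 4 h).
#' @param route Optional route tag for the output.
#' @return data.frame shortlist ordered by size (descending, largest first)
#'   and rank within size.
#' @export
select_representatives <- function(evals, window_hours = 4,
                                   route = NA_character_) {
  tab <- if (is.data.frame(evals)) evals else evaluation_table(evals)
  out <- list()
  for (s in sort(unique(tab$size), decreasing = TRUE)) {
    sub <- tab[tab$size == s, ]
    sub <- sub[order(sub$pae95, sub$rmse, sub$tmax, sub$design), ]
    picks <- sub[1, , drop = FALSE]
    restr <- sub[sub$includes_c0 & sub$tmax <= window_hours, , drop = FALSE]
    if (nrow(restr))
      picks <- rbind(picks, utils::head(restr, 3))
    picks <- picks[!duplicated(picks$design), , drop = FALSE]
    picks$rank <- seq_len(nrow(picks))
    out[[length(out) + 1]] <- picks
  }
  res <- do.call(rbind, out)
  res$route <- route
  rownames(res) <- NULL
  res
}
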