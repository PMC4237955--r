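# Orchestration and publication-shaped reporting: a run configuration that
# round-trips through YAML, a pipeline driver producing the model-by-design
# performance matrix, per-design detail, fit reports and a manifest, and
# per-observation diagnostic exports.

.model_to_list <- function(pop) {
  list(theta = lapply(pop$theta, as.numeric),
       iiv = as.list(pop$iiv),
       corr_cl_q = pop$corr_cl_q,
       vc_slope = pop$vc_slope,
       error = list(kind = pop$error$kind, sigma_add = pop$error$sigma_add,
                    sigma_prop = pop$error$sigma_prop),
       covariates = lapply(pop$covariates, function(tm) list(
         param = tm$param, covariate = tm$covariate, form = tm$form,
         coef = as.list(tm$coef), center = tm$center)),
       allometry = pop$allometry)
}

.model_from_list <- function(spec) {
  covs <- lapply(spec$covariates, function(tm)
    covariate_term(tm$param, tm$covariate, tm$form, coef = unlist(tm$coef),
                   center = if (is.null(tm$center)) NA_real_ else tm$center))
  population_model(
    theta = spec$theta, iiv = unlist(spec$iiv),
    corr_cl_q = spec$corr_cl_q, vc_slope = spec$vc_slope,
    error = error_model(spec$error$kind, sigma_add = spec$error$sigma_add,
                        sigma_prop = spec$error$sigma_prop),
    covariates = covs, allometry = spec$allometry)
}

#' Pipeline run configuration
#'
#' @param cohort A [cohort_spec()] describing the simulated cohort.
#' @param models Named list of [population_model()]s to compare (structural
#'   and covariate variants).
#' @param generator Generating model(s) passed to [generate_dataset()]
#'   (`NULL` = published defaults).
#' @param max_points,window_hours,require_c0 LSS search settings.
#' @param targets AUC reference(s) to evaluate: subset of
#'   `c("observed", "underlying")`.
#' @param refit Per-fold population refits in the cross-validation (the full
#'   procedure); `FALSE` reuses the full-data fit (fast approximation).
#' @param seed Seed governing every stochastic stage (bootstrap streams are
#'   derived from it).
#' @param fit_control Control list forwarded to [fit_population()].
#' @param outdir Output directory for the report bundle.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort, models, generator = NULL, max_points = 4,
                       window_hours = 4, require_c0 = TRUE,
                       targets = c("observed", "underlying"), refit = FALSE,
                       seed = 1, fit_control = list(),
                       outdir = tempfile("blss_run_")) {
  stopifnot(inherits(cohort, "cohort_spec"), is.list(models),
            length(models) >= 1, !is.null(names(models)))
  for (m in models) stopifnot(inherits(m, "population_model"))
  targets <- match.arg(targets, several.ok = TRUE)
  structure(list(cohort = cohort, models = models, generator = generator,
                 max_points = max_points, window_hours = window_hours,
                 require_c0 = require_c0, targets = targets, refit = refit,
                 seed = as.integer(seed), fit_control = fit_control,
                 outdir = outdir),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `path` / the restored [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  gen <- config$generator
  gen_spec <- if (is.null(gen)) NULL
    else if (inherits(gen, "population_model")) .model_to_list(gen)
    else lapply(gen, .model_to_list)
  spec <- list(
    cohort = unclass(config$cohort),
    models = lapply(config$models, .model_to_list),
    generator = gen_spec,
    max_points = config$max_points, window_hours = config$window_hours,
    require_c0 = config$require_c0, targets = config$targets,
    refit = config$refit, seed = config$seed,
    fit_control = config$fit_control, outdir = config$outdir)
  yaml::write_yaml(spec, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  spec <- yaml::read_yaml(path)
  co <- spec$cohort
  cohort <- cohort_spec(
    n_iv_profiles = co$n_iv_profiles, n_po_profiles = co$n_po_profiles,
    seed = co$seed, dose_iv = co$dose_iv, dose_po = co$dose_po,
    grid_iv = unlist(co$grid_iv), grid_po = unlist(co$grid_po),
    ranges_iv = lapply(co$ranges_iv, unlist),
    ranges_po = lapply(co$ranges_po, unlist),
    lloq = co$lloq, uloq = co$uloq, bql = co$bql)
  gen <- spec$generator
  generator <- if (is.null(gen)) NULL
    else if (!is.null(gen$theta)) .model_from_list(gen)
    else lapply(gen, .model_from_list)
  run_config(cohort = cohort,
             models = lapply(spec$models, .model_from_list),
             generator = generator, max_points = spec$max_points,
             window_hours = spec$window_hours, require_c0 = spec$require_c0,
             targets = unlist(spec$targets), refit = spec$refit,
             seed = spec$seed,
             fit_control = if (is.null(spec$fit_control)) list()
                           else spec$fit_control,
             outdir = spec$outdir)
}

#' Per-observation diagnostic tables from a population fit
#'
#' Exports, for every observation record, the population prediction (PRED,
#' all random effects at zero), the individual prediction (IPRED, MAP random
#' effects), raw residuals against both, and the standardised individual
#' residual (residual over the residual-error SD at IPRED) for external
#' plotting.
#'
#' @param fit A `pop_fit` from [fit_population()].
#' @param dataset The dataset that was fitted.
#' @return data.frame with one row per observation.
#' @export
diagnostics_export <- function(fit, dataset) {
  stopifnot(inherits(fit, "pop_fit"))
  subjects <- as_subjects(dataset)
  model <- fit$model
  out <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    ctx <- .make_ctx(model, s)
    pred <- .ctx_predict(ctx, numeric(4), s$times)
    ipred <- fit$ipred[[i]]
    sdv <- sqrt(pmax(residual_variance(model$error, ipred), .V_FLOOR))
    out[[i]] <- data.frame(
      ID = s$id, TIME = s$times, DV = s$y, PRED = pred, IPRED = ipred,
      RES = s$y - pred, IRES = s$y - ipred,
      IWRES = (s$y - ipred) / sdv, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Run the full simulation-to-report pipeline
#'
#' Generates the configured cohort, then for every model variant: fits it,
#' sweeps all limited sampling designs per route under cross-validation,
#' selects representative designs, and evaluates the requested AUC targets.
#' Writes publication-shaped CSVs (`table2_like.csv`: model-by-design 95th
#' PAE% shortlist matrix; `table3_like.csv`: per-design detail with CIs and
#' error categories for each target; `table4_like.csv`: fit estimates;
#' `dataset.csv`/`dataset_truth.csv`; `diagnostics_<model>.csv`) plus a
#' `manifest.yaml` recording seeds, versions, timings and per-stage status.
#' Model-variant failures are isolated and recorded, not fatal.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the dataset, per-model fits and evaluation
#'   tables, the shortlist tables, and the manifest.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("bayeslss")),
                   r_version = R.version.string,
                   stages = list(), timings = list())

  say("generating cohort (seed %d)", config$cohort$seed)
  dataset <- generate_dataset(config$cohort, model = config$generator)
  write_pk_dataset(dataset, file.path(config$outdir, "dataset"))
  manifest$stages$simulate <- "ok"

  routes <- intersect(c("IV", "PO"),
                      unique(vapply(as_subjects(dataset), `[[`, "", "route")))
  fits <- list()
  eval_tabs <- list()
  shortlists <- list()
  table3 <- list()
  for (mn in names(config$models)) {
    st <- Sys.time()
    res <- tryCatch({
      say("fitting model %s", mn)
      fit <- fit_population(dataset, config$models[[mn]],
                            control = config$fit_control)
      fits[[mn]] <- fit
      utils::write.csv(diagnostics_export(fit, dataset),
                       file.path(config$outdir,
                                 sprintf("diagnostics_%s.csv", mn)),
                       row.names = FALSE)
      for (rt in routes) {
        grid <- if (rt == "IV") config$cohort$grid_iv else config$cohort$grid_po
        designs <- enumerate_lss(grid, config$max_points, route = rt)
        for (tg in config$targets) {
          say("  LSS sweep: %s / %s AUC (%d designs)", rt, tg, length(designs))
          evals <- loocv_evaluate(dataset, config$models[[mn]], designs,
                                  refit = config$refit, target = tg,
                                  route = rt, fitted = fit,
                                  fit_control = config$fit_control,
                                  boot_seed = config$seed)
          tab <- evaluation_table(evals)
          tab$model <- mn
          tab$route <- rt
          key <- paste(mn, rt, tg, sep = "/")
          eval_tabs[[key]] <- tab
          if (tg == "observed") {
            shortlists[[paste(mn, rt, sep = "/")]] <-
              cbind(model = mn,
                    select_representatives(tab, config$window_hours, route = rt))
          }
          sel <- shortlists[[paste(mn, rt, sep = "/")]]
          if (!is.null(sel)) {
            det <- tab[tab$design %in% sel$design, , drop = FALSE]
            ekey <- vapply(evals, `[[`, "", "label")
            det$rmse_lo <- vapply(det$design, function(d) evals[[match(d, ekey)]]$rmse_ci[1], 0)
            det$rmse_hi <- vapply(det$design, function(d) evals[[match(d, ekey)]]$rmse_ci[2], 0)
            det$me_lo <- vapply(det$design, function(d) evals[[match(d, ekey)]]$me_ci[1], 0)
            det$me_hi <- vapply(det$design, function(d) evals[[match(d, ekey)]]$me_ci[2], 0)
            table3[[key]] <- det
          }
        }
      }
      "ok"
    }, error = function(e) paste("failed:", conditionMessage(e)))
    manifest$stages[[paste0("model_", mn)]] <- res
    manifest$timings[[paste0("model_", mn)]] <-
      as.numeric(difftime(Sys.time(), st, units = "secs"))
  }

  # shortlist matrix: representative designs x models (95th PAE%, observed)
  t2 <- do.call(rbind, shortlists)
  if (!is.null(t2)) {
    utils::write.csv(t2, file.path(config$outdir, "table2_like.csv"),
                     row.names = FALSE)
  }
  t3 <- do.call(rbind, table3)
  if (!is.null(t3))
    utils::write.csv(t3, file.path(config$outdir, "table3_like.csv"),
                     row.names = FALSE)
  t4 <- do.call(rbind, lapply(names(fits), function(mn) {
    m <- fits[[mn]]$model
    data.frame(model = mn, ofv = fits[[mn]]$ofv,
               t(unlist(m$theta)),
               t(stats::setNames(m$iiv, paste0("iiv_", names(m$iiv)))),
               sigma_add = m$error$sigma_add, sigma_prop = m$error$sigma_prop,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(t4))
    utils::write.csv(t4, file.path(config$outdir, "table4_like.csv"),
                     row.names = FALSE)

  manifest$timings$total <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$seeds_consumed <- list(cohort = config$cohort$seed,
                                  bootstrap = config$seed)
  yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))
  invisible(list(dataset = dataset, fits = fits, evaluations = eval_tabs,
                 shortlists = shortlists, table3 = t3, manifest = manifest))
}
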