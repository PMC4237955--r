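# Model specification files: a structured YAML representation of a
# population_model that round-trips losslessly.

#' Write a population model to a YAML specification file
#'
#' @param pop A [population_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(pop, path) {
  stopifnot(inherits(pop, "population_model"))
  spec <- list(
    theta = lapply(pop$theta, as.numeric),
    iiv = as.list(pop$iiv),
    corr_cl_q = pop$corr_cl_q,
    vc_slope = pop$vc_slope,
    error = list(kind = pop$error$kind,
                 sigma_add = pop$error$sigma_add,
                 sigma_prop = pop$error$sigma_prop),
    covariates = lapply(pop$covariates, function(tm) list(
      param = tm$param, covariate = tm$covariate, form = tm$form,
      coef = as.list(tm$coef), center = tm$center)),
    allometry = pop$allometry)
  yaml::write_yaml(spec, path, precision = 15)
  invisible(path)
}

#' Read a population model from a YAML specification file
#'
#' @param path File written by [write_model_spec()].
#' @return A [population_model()].
#' @export
read_model_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  covs <- lapply(spec$covariates, function(tm) {
    coef <- unlist(tm$coef)
    covariate_term(tm$param, tm$covariate, tm$form, coef = coef,
                   center = if (is.null(tm$center)) NA_real_ else tm$center)
  })
  population_model(
    theta = spec$theta,
    iiv = unlist(spec$iiv),
    corr_cl_q = spec$corr_cl_q,
    vc_slope = spec$vc_slope,
    error = error_model(spec$error$kind, sigma_add = spec$error$sigma_add,
                        sigma_prop = spec$error$sigma_prop),
    covariates = covs,
    allometry = spec$allometry)
}
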