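prior_spec_names <- c("final", paste0("model", 1:7))

#' Precision-prior specification
#'
#' Each specification maps the GLM-derived scale statistics to the gamma
#' shape and rate of the per-cell EAFR precision, with its own grouping:
#'
#' \describe{
#'   \item{final}{G(1/sigma_e, 2 sigma_e): SD of standard errors by
#'     education.}
#'   \item{model1}{G(alpha, beta) moment-matched to the pooled standard
#'     errors via their variance-to-mean ratio (alpha = mean^2/variance,
#'     beta = mean/variance).}
#'   \item{model2}{G(1/mu_e, sigma2_e): mean and variance of standard errors
#'     by education.}
#'   \item{model3}{G(1/sigma2_e, sigma2_e): variance of standard errors by
#'     education.}
#'   \item{model4}{G(1/sigma2, sigma2): pooled variance of standard errors.}
#'   \item{model5}{G(1/sigma, sigma2): variance of the predicted estimates.}
#'   \item{model6}{G(1/sigma_ae, sigma_ae): SD of standard errors by age and
#'     education (28 groups).}
#'   \item{model7}{G(1/sigma_e, sigma_e): SD of standard errors by
#'     education.}
#' }
#'
#' @param name One of `"final"`, `"model1"` ... `"model7"`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(name) {
  name <- match.arg(name, prior_spec_names)
  structure(list(name = name), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec> ", x$name, "\n", sep = "")
  invisible(x)
}

#' All eight precision-prior specifications
#'
#' Validates that every specification instantiates with strictly positive
#' shape and rate from the supplied statistics.
#'
#' @param stats A [derive_prior_statistics()] result.
#' @return List of 8 [prior_spec()] objects (final model first).
#' @export
enumerate_prior_specs <- function(stats) {
  specs <- lapply(prior_spec_names, prior_spec)
  for (sp in specs) prior_shape_rate(sp, stats) # errors on bad statistics
  specs
}

# gamma shape/rate per grouping unit for a spec; returns list(shape, rate,
# grouping) where grouping is "education", "age_education" or "pooled"
prior_shape_rate <- function(spec, stats) {
  s <- stats
  out <- switch(spec$name,
    final = list(shape = 1 / s$sigma_e, rate = 2 * s$sigma_e,
                 grouping = "education", statistic = "sigma_e"),
    model1 = list(shape = s$mu_pooled / s$var_mean_ratio,
                  rate = 1 / s$var_mean_ratio,
                  grouping = "pooled", statistic = "var_mean_ratio"),
    model2 = list(shape = 1 / s$mu_e, rate = s$sigma2_e,
                  grouping = "education", statistic = "mu_e/sigma2_e"),
    model3 = list(shape = 1 / s$sigma2_e, rate = s$sigma2_e,
                  grouping = "education", statistic = "sigma2_e"),
    model4 = list(shape = 1 / s$sigma2_pooled, rate = s$sigma2_pooled,
                  grouping = "pooled", statistic = "sigma2_pooled"),
    model5 = list(shape = 1 / sqrt(s$sigma2_est), rate = s$sigma2_est,
                  grouping = "pooled", statistic = "sigma2_est"),
    model6 = list(shape = 1 / s$sigma_ae, rate = s$sigma_ae,
                  grouping = "age_education", statistic = "sigma_ae"),
    model7 = list(shape = 1 / s$sigma_e, rate = s$sigma_e,
                  grouping = "education", statistic = "sigma_e"))
  bad <- !is.finite(out$shape) | !is.finite(out$rate) |
    out$shape <= 0 | out$rate <= 0
  if (any(bad)) {
    stop("prior spec '", spec$name, "' cannot be instantiated: statistic ",
         out$statistic, " yields non-positive gamma shape or rate",
         call. = FALSE)
  }
  out
}

# expand a spec's shape/rate to the full-lattice grids (lattice order)
instantiate_prior <- function(spec, stats, lattice) {
  sr <- prior_shape_rate(spec, stats)
  grid <- lattice_cells(lattice)
  expand <- function(x) {
    switch(sr$grouping,
      pooled = rep(x, nrow(grid)),
      education = unname(x[grid$education]),
      age_education = x[cbind(grid$age_group, grid$education)])
  }
  list(shape = expand(sr$shape), rate = expand(sr$rate), spec = spec)
}
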