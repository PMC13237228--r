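#' Cleaning rules for survey rate observations
#'
#' @param max_births_higher_ed Rows with education "Higher Education" and a
#'   reported birth count above this are removed (default 30).
#' @param outlier_rate_ceiling Rows with a rate above this hard ceiling
#'   (births per woman per year) are removed (default 1).
#' @param mad_multiplier Rows whose rate deviates from the
#'   country-education-age median by more than this many robust (MAD)
#'   deviations are removed (default 5).
#' @return An object of class `clean_config`.
#' @export
clean_config <- function(max_births_higher_ed = 30,
                         outlier_rate_ceiling = 1.0,
                         mad_multiplier = 5) {
  stopifnot(max_births_higher_ed > 0, outlier_rate_ceiling > 0,
            mad_multiplier > 0)
  structure(list(max_births_higher_ed = max_births_higher_ed,
                 outlier_rate_ceiling = outlier_rate_ceiling,
                 mad_multiplier = mad_multiplier),
            class = "clean_config")
}

#' Clean survey observations
#'
#' Applies three deterministic filters: (i) higher-education rows reporting
#' more births than plausible for that group; (ii) rates above a hard
#' ceiling; (iii) robust outliers relative to the country-education-age
#' median. The removed rows, tagged by rule, are attached as attribute
#' `"removed"`.
#'
#' @param raw Survey observation table (columns `country`, `education`,
#'   `age_group`, `value`; `births` optional).
#' @param cfg A [clean_config()].
#' @return The retained rows, with attribute `removed`.
#' @export
clean_observations <- function(raw, cfg = clean_config()) {
  rule <- rep(NA_character_, nrow(raw))
  if ("births" %in% names(raw)) {
    hit <- raw$education == "Higher Education" & !is.na(raw$births) &
      raw$births > cfg$max_births_higher_ed
    rule[hit] <- "higher_ed_birth_count"
  }
  hit <- is.na(rule) & raw$value > cfg$outlier_rate_ceiling
  rule[hit] <- "rate_ceiling"

  # iterate the robust rule to a fixed point so cleaning is idempotent
  key <- cell_key(raw, c("country", "education", "age_group"))
  repeat {
    live <- is.na(rule)
    med <- stats::ave(ifelse(live, raw$value, NA), key,
                      FUN = function(v) stats::median(v, na.rm = TRUE))
    madv <- stats::ave(ifelse(live, raw$value, NA), key,
                       FUN = function(v) stats::mad(v, na.rm = TRUE))
    hit <- live & is.finite(madv) & madv > 0 &
      abs(raw$value - med) > cfg$mad_multiplier * madv
    if (!any(hit)) break
    rule[hit] <- "robust_outlier"
  }

  removed <- raw[!is.na(rule), , drop = FALSE]
  if (nrow(removed)) removed$rule <- rule[!is.na(rule)]
  out <- raw[is.na(rule), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

glm_formula <- function(spec, response) {
  n <- vapply(list(education = spec$education_levels,
                   region = unique(unname(spec$region_assignment)),
                   age_group = spec$age_groups,
                   country = spec$countries,
                   period = spec$periods), length, integer(1))
  keep <- names(n)[n > 1]
  mains <- c("education", "region", "age_group", "country", "period")
  twoway <- list(c("education", "age_group"), c("period", "age_group"),
                 c("region", "age_group"), c("region", "period"),
                 c("region", "country"))
  terms <- intersect(mains, keep)
  for (tw in twoway) {
    if (all(tw %in% keep)) terms <- c(terms, paste(tw, collapse = ":"))
  }
  if (!length(terms)) terms <- "1"
  stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
}

#' Fit the initialization GLM and complete the rate lattice
#'
#' Step 1 of the pipeline: fits a generalized linear model with main effects
#' for education, region, age group, country and period and the two-way
#' interactions education:age, period:age, region:age, region:period and
#' region:country, then predicts the education- and age-specific rate on the
#' complete lattice (including periods and cells with no observations) with a
#' per-cell standard error of prediction.
#'
#' When birth counts and exposures are available the model is Poisson with a
#' log link and a log-exposure offset; otherwise a Gaussian model is fitted
#' to log(rate + 1e-6). Either way, predictions and their standard errors are
#' returned on the rate scale (delta method from the linear predictor).
#' Interaction levels that are inestimable from the observed coverage are
#' aliased and dropped from the prediction (treated as zero), so every cell
#' receives a finite positive center.
#'
#' @param obs Cleaned survey observation table.
#' @param spec A [lattice_spec()] defining the target lattice.
#' @param family `"auto"` (default: Poisson when counts and exposures are
#'   present), `"poisson"` or `"gaussian"`.
#' @return An object of class `glm_init`: list with rate grids `predicted`
#'   and `se`, the fitted `family`, `deviance`, `converged`, `n_aliased` and
#'   the lattice `spec`.
#' @export
fit_glm_init <- function(obs, spec, family = c("auto", "poisson",
                                               "gaussian")) {
  family <- match.arg(family)
  have_counts <- all(c("births", "exposure") %in% names(obs)) &&
    !anyNA(obs$births) && !anyNA(obs$exposure) && all(obs$exposure > 0)
  if (family == "auto") family <- if (have_counts) "poisson" else "gaussian"
  if (family == "poisson" && !have_counts) {
    stop("poisson initialization needs complete births and exposure columns",
         call. = FALSE)
  }
  for (lev in c("education", "age_group", "country", "period")) {
    match_vocabulary(obs[[lev]],
                     switch(lev, education = spec$education_levels,
                            age_group = spec$age_groups,
                            country = spec$countries,
                            period = spec$periods), lev)
  }

  regions <- unique(unname(spec$region_assignment))
  as_factors <- function(df) {
    df$education <- factor(df$education, levels = spec$education_levels)
    df$age_group <- factor(df$age_group, levels = spec$age_groups)
    df$country <- factor(df$country, levels = spec$countries)
    df$period <- factor(df$period, levels = spec$periods)
    df$region <- factor(unname(spec$region_assignment[as.character(df$country)]),
                        levels = regions)
    df
  }
  dat <- as_factors(obs)

  # design matrices are built by hand (not via glm()) so that factor levels
  # never observed in the surveys still receive design columns: aliased
  # (all-zero or rank-deficient) columns get NA coefficients and drop out of
  # the prediction, giving every lattice cell a finite center
  eps <- 1e-6
  form <- glm_formula(spec, "")
  tt <- stats::terms(form)
  mf <- stats::model.frame(tt, dat)
  X <- stats::model.matrix(tt, mf)
  if (family == "poisson") {
    y <- dat$births
    fam <- stats::poisson()
    off <- log(dat$exposure)
  } else {
    y <- log(dat$value + eps)
    fam <- stats::gaussian()
    off <- rep(0, nrow(dat))
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam, offset = off,
                   control = stats::glm.control(maxit = 100)))
  if (!isTRUE(fit$converged)) {
    stop("initialization GLM did not converge (deviance ",
         signif(fit$deviance, 6), ")", call. = FALSE)
  }
  beta <- fit$coefficients
  aliased <- is.na(beta)
  beta[aliased] <- 0
  rank <- fit$rank
  piv <- fit$qr$pivot[seq_len(rank)]
  Rmat <- fit$qr$qr[seq_len(rank), seq_len(rank), drop = FALSE]
  Rmat[lower.tri(Rmat)] <- 0
  V <- chol2inv(Rmat)
  dispersion <- if (family == "poisson") 1 else {
    sum(fit$residuals^2 * fit$weights) / max(fit$df.residual, 1)
  }

  grid <- lattice_cells(spec)
  grid$region <- unname(spec$region_assignment[grid$country])
  newdata <- as_factors(grid)
  Xn <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  Xn <- Xn[, colnames(X), drop = FALSE]
  eta <- as.numeric(Xn %*% beta)
  Xp <- Xn[, piv, drop = FALSE]
  se_eta <- sqrt(pmax(rowSums((Xp %*% V) * Xp) * dispersion, 0))
  rate <- if (family == "poisson") exp(eta) else pmax(exp(eta) - eps, 1e-8)
  # delta method: SE on the rate scale from the linear-predictor scale
  se_rate <- exp(eta) * se_eta

  predicted <- grid[c("country", "region", "period", "age_group",
                      "education")]
  predicted$value <- pmax(rate, 1e-8)
  se_grid <- predicted
  se_grid$value <- se_rate

  structure(list(predicted = predicted, se = se_grid, family = family,
                 deviance = fit$deviance, converged = fit$converged,
                 n_aliased = sum(aliased), spec = spec),
            class = "glm_init")
}

#' Reassemble an initialization object from stored lattices
#'
#' Rebuilds the object returned by [fit_glm_init()] from its predicted-rate
#' and standard-error grids, e.g. after reading them back from CSV.
#'
#' @param predicted Rate grid of predicted EAFR on the full lattice.
#' @param se Grid of prediction standard errors on the full lattice.
#' @param spec The [lattice_spec()].
#' @param family Family label of the original fit.
#' @return An object of class `glm_init`.
#' @export
as_glm_init <- function(predicted, se, spec, family = "poisson") {
  for (g in list(predicted, se)) {
    rep <- validate_lattice(g, spec)
    if (nrow(rep$missing) || nrow(rep$duplicated)) {
      stop("grid does not cover the lattice exactly: ",
           nrow(rep$missing), " missing, ", nrow(rep$duplicated),
           " duplicated cells", call. = FALSE)
    }
  }
  structure(list(predicted = predicted, se = se, family = family,
                 deviance = NA_real_, converged = NA, n_aliased = NA_integer_,
                 spec = spec),
            class = "glm_init")
}

#' @export
print.glm_init <- function(x, ...) {
  cat("<glm_init> ", x$family, " fit, deviance ", signif(x$deviance, 6),
      ", ", x$n_aliased, " aliased coefficients, ",
      nrow(x$predicted), " predicted cells\n", sep = "")
  invisible(x)
}

#' Scale statistics for the precision hyperpriors
#'
#' Derives from the completed GLM lattice every scale statistic used by the
#' eight precision-prior specifications: standard deviations, means and
#' variances of the prediction standard errors grouped by education, by age
#' and education, and pooled; the variance of the predicted rates; the
#' variance-to-mean ratio of the standard errors; and the standard deviation
#' of the derived total rate for the highest education level.
#'
#' @param init A [fit_glm_init()] result.
#' @return An object of class `prior_statistics`.
#' @export
derive_prior_statistics <- function(init) {
  stopifnot(inherits(init, "glm_init"))
  se <- init$se$value
  edu <- init$se$education
  levels_e <- init$spec$education_levels
  levels_a <- init$spec$age_groups

  group_stat <- function(groups, levels, fun, what) {
    vapply(levels, function(l) {
      v <- se[groups == l]
      if (!length(v)) stop("no standard errors in group: ", what, " ", l,
                           call. = FALSE)
      fun(v)
    }, numeric(1))
  }
  sigma_e <- group_stat(edu, levels_e, stats::sd, "education")
  mu_e <- group_stat(edu, levels_e, mean, "education")
  sigma2_e <- group_stat(edu, levels_e, stats::var, "education")

  ae <- paste(init$se$age_group, edu, sep = "\r")
  ae_levels <- as.vector(outer(levels_a, levels_e, paste, sep = "\r"))
  sigma_ae <- group_stat(ae, ae_levels, stats::sd, "age x education")
  sigma_ae <- matrix(sigma_ae, nrow = length(levels_a),
                     dimnames = list(levels_a, levels_e))

  # derived total rate for the highest education level, per country-period
  top <- levels_e[length(levels_e)]
  sub <- init$predicted[init$predicted$education == top, , drop = FALSE]
  key <- cell_key(sub, c("country", "period"))
  etfr_top <- 5 * rowsum(sub$value, key)[, 1]

  mu_pooled <- mean(se)
  sigma2_pooled <- stats::var(se)
  structure(list(sigma_e = sigma_e, mu_e = mu_e, sigma2_e = sigma2_e,
                 sigma_pooled = stats::sd(se), sigma2_pooled = sigma2_pooled,
                 mu_pooled = mu_pooled,
                 var_mean_ratio = sigma2_pooled / mu_pooled,
                 sigma2_est = stats::var(init$predicted$value),
                 sigma_ae = sigma_ae,
                 sigma_etfr_e4 = stats::sd(etfr_top),
                 education_levels = levels_e, age_groups = levels_a),
            class = "prior_statistics")
}

#' @export
print.prior_statistics <- function(x, ...) {
  cat("<prior_statistics>\n")
  cat("  sigma_e:", paste(signif(x$sigma_e, 4), collapse = " "), "\n")
  cat("  mu_e:   ", paste(signif(x$mu_e, 4), collapse = " "), "\n")
  cat("  pooled SD ", signif(x$sigma_pooled, 4), ", var/mean ratio ",
      signif(x$var_mean_ratio, 4), ", sd(ETFR top) ",
      signif(x$sigma_etfr_e4, 4), "\n", sep = "")
  invisible(x)
}

#' Write prior statistics as a small CSV
#'
#' @param stats A [derive_prior_statistics()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_prior_statistics <- function(stats, path) {
  rows <- rbind(
    data.frame(statistic = "sigma_e", group = names(stats$sigma_e),
               value = unname(stats$sigma_e)),
    data.frame(statistic = "mu_e", group = names(stats$mu_e),
               value = unname(stats$mu_e)),
    data.frame(statistic = "sigma2_e", group = names(stats$sigma2_e),
               value = unname(stats$sigma2_e)),
    data.frame(statistic = "sigma_ae",
               group = as.vector(outer(rownames(stats$sigma_ae),
                                       colnames(stats$sigma_ae), paste,
                                       sep = " / ")),
               value = as.vector(stats$sigma_ae)),
    data.frame(statistic = c("sigma_pooled", "sigma2_pooled", "mu_pooled",
                             "var_mean_ratio", "sigma2_est",
                             "sigma_etfr_e4"),
               group = "",
               value = c(stats$sigma_pooled, stats$sigma2_pooled,
                         stats$mu_pooled, stats$var_mean_ratio,
                         stats$sigma2_est, stats$sigma_etfr_e4)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
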