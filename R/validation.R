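#' Default holdout fraction ladder
#'
#' @return The fractions 5\%, 10\%, 15\%, 20\% and 30\%.
#' @export
default_holdout_fractions <- function() {
  c(0.05, 0.10, 0.15, 0.20, 0.30)
}

#' Hold out benchmark values
#'
#' Removes benchmark ASFR rows either uniformly at random (a fraction of all
#' rows, unstratified) or by whole countries, for refitting and
#' credible-interval coverage checks.
#'
#' @param benchmark Benchmark table (`country`, `period`, `age_group`,
#'   `value`).
#' @param kind `"random_fraction"` or `"countries"`.
#' @param fraction Fraction in (0, 1) of rows to remove (random_fraction
#'   kind); `round(fraction * nrow)` rows are held out.
#' @param countries Countries whose benchmark rows are all removed
#'   (countries kind).
#' @param seed Integer seed.
#' @return List with elements `plan` (class `holdout_plan`, carrying the
#'   held-out rows) and `benchmark` (the reduced table).
#' @export
make_holdout <- function(benchmark, kind = c("random_fraction", "countries"),
                         fraction = NULL, countries = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "random_fraction") {
    if (is.null(fraction) || fraction <= 0 || fraction >= 1) {
      stop("fraction must lie in (0, 1)", call. = FALSE)
    }
    n_out <- round(fraction * nrow(benchmark))
    idx <- withr_seed(seed, sample.int(nrow(benchmark), n_out))
    label <- sprintf("random %g%%", 100 * fraction)
  } else {
    missing_c <- setdiff(countries, unique(benchmark$country))
    if (length(missing_c)) {
      stop("unknown countr(ies) in holdout: ",
           paste(missing_c, collapse = ", "), call. = FALSE)
    }
    idx <- which(benchmark$country %in% countries)
    label <- paste("countries:", paste(countries, collapse = ", "))
  }
  held <- benchmark[idx, , drop = FALSE]
  reduced <- benchmark[setdiff(seq_len(nrow(benchmark)), idx), ,
                       drop = FALSE]
  rownames(held) <- rownames(reduced) <- NULL
  plan <- structure(list(kind = kind, fraction = fraction,
                         countries = countries, label = label,
                         held_out = held, seed = as.integer(seed)),
                    class = "holdout_plan")
  list(plan = plan, benchmark = reduced)
}

#' @export
print.holdout_plan <- function(x, ...) {
  cat("<holdout_plan> ", x$label, " (", nrow(x$held_out),
      " rows held out)\n", sep = "")
  invisible(x)
}

#' Credible-interval coverage of held-out benchmark values
#'
#' For each interval level, counts how many held-out benchmark ASFR values
#' fall inside the central equal-tailed posterior interval of the
#' corresponding aggregated ASFR parameter.
#'
#' @param draws A [run_mcmc()] result (from the refit without the held-out
#'   rows).
#' @param held_out Benchmark rows that were removed.
#' @param levels Interval probabilities (default 50\%, 80\%, 90\%).
#' @return An object of class `coverage_report`: data frame with columns
#'   `level`, `covered`, `total`, `fraction`, plus a per-country breakdown
#'   in attribute `"by_country"`.
#' @export
coverage <- function(draws, held_out, levels = c(0.5, 0.8, 0.9)) {
  stopifnot(inherits(draws, "fert_draws"))
  keys <- cell_key(held_out, c("country", "period", "age_group"))
  pos <- match(keys, cell_key(draws$cells$asfr,
                              c("country", "period", "age_group")))
  if (anyNA(pos)) {
    stop("held-out cell(s) missing from the posterior draws: ",
         paste(utils::head(gsub("\r", "/", keys[is.na(pos)]), 5),
               collapse = ", "), call. = FALSE)
  }
  sub <- draws$asfr[, pos, drop = FALSE]
  rows <- list(); by_country <- list()
  for (lv in sort(levels)) {
    q <- apply(sub, 2, stats::quantile,
               probs = c((1 - lv) / 2, 1 - (1 - lv) / 2), names = FALSE)
    inside <- held_out$value >= q[1, ] & held_out$value <= q[2, ]
    rows[[length(rows) + 1]] <- data.frame(
      level = lv, covered = sum(inside), total = length(inside),
      fraction = mean(inside))
    bc <- rowsum(cbind(covered = as.numeric(inside), total = 1),
                 held_out$country)
    by_country[[length(by_country) + 1]] <- data.frame(
      country = rownames(bc), level = lv, covered = bc[, "covered"],
      total = bc[, "total"], fraction = bc[, "covered"] / bc[, "total"],
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "by_country") <- do.call(rbind, by_country)
  class(out) <- c("coverage_report", "data.frame")
  out
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report>\n")
  print.data.frame(x)
  invisible(x)
}

#' Refit under a set of holdout plans and report coverage
#'
#' For each plan, rebuilds the model on the reduced benchmark, reruns the
#' sampler and computes held-out coverage. Each plan is fitted with the same
#' seed policy, so identical plans give identical rows.
#'
#' @param inputs A [model_inputs()] object built on the full benchmark.
#' @param plans List of plans from [make_holdout()] (each element the list
#'   returned by it, or a bare `holdout_plan` -- then the reduced benchmark
#'   is reconstructed from `inputs$benchmark`).
#' @param levels Interval probabilities.
#' @param chains,warmup,iterations,seed Sampler settings, passed to
#'   [run_mcmc()].
#' @return Data frame with one row per plan and level: `plan`, `level`,
#'   `covered`, `total`, `fraction`.
#' @export
run_validation_suite <- function(inputs, plans, levels = c(0.5, 0.8, 0.9),
                                 chains = 2, warmup = 500,
                                 iterations = 1000, seed = 1L) {
  stopifnot(inherits(inputs, "model_inputs"))
  rows <- list()
  for (pl in plans) {
    if (inherits(pl, "holdout_plan")) {
      keys <- cell_key(inputs$benchmark,
                       c("country", "period", "age_group"))
      out_keys <- cell_key(pl$held_out,
                           c("country", "period", "age_group"))
      reduced <- inputs$benchmark[!(keys %in% out_keys), , drop = FALSE]
      pl <- list(plan = pl, benchmark = reduced)
    }
    red_inputs <- model_inputs(init = inputs$init,
                               benchmark = pl$benchmark,
                               weights = inputs$weights,
                               prior_stats = inputs$prior_stats,
                               prior_spec = inputs$prior_spec,
                               prev_etfr = inputs$prev_etfr,
                               etfr_trunc = inputs$etfr_trunc)
    fit <- run_mcmc(build_model(red_inputs), chains = chains,
                    warmup = warmup, iterations = iterations, seed = seed)
    cov <- coverage(fit, pl$plan$held_out, levels = levels)
    cov$plan <- pl$plan$label
    rows[[length(rows) + 1]] <- cov[c("plan", "level", "covered", "total",
                                      "fraction")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Agreement with an alternative benchmark
#'
#' Computes the fraction of an alternative benchmark's ASFR values
#' (country-period-age combinations) that fall inside the posterior credible
#' intervals of a fitted model, including the 95\% level.
#'
#' @param draws A [run_mcmc()] result.
#' @param alt Alternative benchmark table on the same lattice.
#' @param levels Interval probabilities (default adds 95\%).
#' @return A [coverage()]-style report.
#' @export
compare_alt_benchmark <- function(draws, alt,
                                  levels = c(0.5, 0.8, 0.9, 0.95)) {
  coverage(draws, alt, levels = levels)
}

#' Simulate a world from the model's own generative process
#'
#' Draws per-cell precisions from the configured gamma prior, true EAFR from
#' the positive-truncated normal around the GLM centers, and sets the
#' benchmark to the exact weight-aggregated truth (noise-free). Used for
#' calibration checks: refitting such a world, the credible intervals for
#' the true EAFR should attain close to nominal coverage.
#'
#' @param inputs A [model_inputs()] object.
#' @param seed Integer seed.
#' @return List with `eafr_true` (rate grid), `benchmark` (noise-free
#'   aggregated table) and `tau` (the drawn precisions, lattice order).
#' @export
simulate_from_model <- function(inputs, seed = 1L) {
  stopifnot(inherits(inputs, "model_inputs"))
  spec <- inputs$spec
  pr <- instantiate_prior(inputs$prior_spec, inputs$prior_stats, spec)
  dhs <- align_to_lattice(inputs$init$predicted, spec, "GLM predictions")
  w <- align_to_lattice(inputs$weights, spec, "weights")
  n <- length(dhs)
  res <- withr_seed(seed, {
    tau <- stats::rgamma(n, shape = pr$shape, rate = pr$rate)
    sd <- 1 / sqrt(tau)
    p0 <- stats::pnorm(0, mean = dhs, sd = sd)
    u <- stats::runif(n, p0, 1)
    list(tau = tau, eafr = stats::qnorm(u, mean = dhs, sd = sd))
  })
  grid <- lattice_cells(spec)
  grid$value <- pmax(res$eafr, 1e-10)
  key <- cell_key(grid, c("country", "period", "age_group"))
  agg <- rowsum(grid$value * w, key)
  bench <- grid[!duplicated(key), c("country", "period", "age_group")]
  bench$value <- agg[match(unique(key), rownames(agg)), 1]
  rownames(bench) <- NULL
  list(eafr_true = grid, benchmark = bench, tau = res$tau)
}
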