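#' Aggregate education-specific rates to the age-specific marginal
#'
#' The age-specific fertility rate is the education-composition-weighted
#' convex combination of the education-specific rates.
#'
#' @param eafr Numeric vector of education-specific rates for one
#'   country-period-age cell.
#' @param w Weights of the same length, summing to 1.
#' @param tol Tolerance on the weight sum.
#' @return The aggregated rate.
#' @examples
#' aggregate_asfr(c(0.30, 0.25, 0.15, 0.10), c(0.5, 0.3, 0.15, 0.05))
#' @export
aggregate_asfr <- function(eafr, w, tol = 1e-6) {
  stopifnot(length(eafr) == length(w))
  if (abs(sum(w) - 1) > tol) {
    stop("weights must sum to 1 (got ", format(sum(w)), ")", call. = FALSE)
  }
  sum(eafr * w)
}

#' Total fertility rate from an age schedule
#'
#' Five times the sum of the seven five-year age-group rates: the expected
#' number of births over the reproductive span at current rates.
#'
#' @param asfr Numeric vector of 7 age-specific rates (15-19 ... 45-49).
#' @return The total rate (births per woman).
#' @examples
#' derive_tfr(c(0.05, 0.20, 0.22, 0.18, 0.10, 0.04, 0.01))
#' @export
derive_tfr <- function(asfr) {
  if (length(asfr) != 7) {
    stop("expected 7 age-group rates, got ", length(asfr), call. = FALSE)
  }
  5 * sum(asfr)
}

#' Education-specific total fertility rate from an age schedule
#'
#' Identical arithmetic to [derive_tfr()], applied to the age schedule of a
#' single education level.
#'
#' @param eafr Numeric vector of 7 education- and age-specific rates.
#' @return The education-specific total rate.
#' @export
derive_etfr <- function(eafr) {
  derive_tfr(eafr)
}

# values in lattice order (education fastest, then age, period, country)
# -> array indexed [country, period, age, education]
grid_to_array <- function(values, spec) {
  E <- length(spec$education_levels); A <- length(spec$age_groups)
  Y <- length(spec$periods); C <- length(spec$countries)
  aperm(array(values, dim = c(E, A, Y, C)), 4:1)
}

# align a long table carrying `value` onto the complete lattice order
align_to_lattice <- function(grid, spec, what) {
  full <- lattice_cells(spec)
  idx <- match(cell_key(full), cell_key(grid))
  if (anyNA(idx)) {
    miss <- full[is.na(idx), , drop = FALSE]
    stop(what, " is missing ", nrow(miss), " lattice cell(s), e.g. ",
         paste(utils::head(apply(miss, 1, paste, collapse = "/"), 3),
               collapse = ", "), call. = FALSE)
  }
  grid$value[idx]
}

#' Assemble the inputs of the hierarchical model
#'
#' Validates that the GLM initialization, benchmark, weights and optional
#' previously published sub-Saharan-African ETFR live on a common lattice and
#' fixes the benchmark precision.
#'
#' @param init A [fit_glm_init()] result (prior centers and standard
#'   errors).
#' @param benchmark Benchmark ASFR table (`country`, `period`, `age_group`,
#'   `value`). Missing rows are tolerated: cells absent from the benchmark
#'   contribute no benchmarking likelihood (the holdout mechanism).
#' @param weights Weight table on the full lattice, weight sums of 1.
#' @param prior_stats A [derive_prior_statistics()] result.
#' @param prior_spec A [prior_spec()] (default the final model).
#' @param prev_etfr Optional table (`country`, `period`, `education`,
#'   `value`) of previously published ETFR for sub-Saharan-African countries.
#' @param tau_asfr Benchmark precision; by default the reciprocal of the
#'   pooled variance of the benchmark values entering the fit.
#' @param etfr_trunc Support of the ETFR estimates (default `c(0, 10)`).
#' @return An object of class `model_inputs`.
#' @export
model_inputs <- function(init, benchmark, weights, prior_stats,
                         prior_spec = edufert::prior_spec("final"),
                         prev_etfr = NULL, tau_asfr = NULL,
                         etfr_trunc = c(0, 10)) {
  stopifnot(inherits(init, "glm_init"),
            inherits(prior_stats, "prior_statistics"),
            inherits(prior_spec, "prior_spec"))
  spec <- init$spec
  wrep <- validate_lattice(weights, spec, weights = TRUE, tol = 1e-6)
  if (!wrep$ok) {
    stop("weight table invalid: ", nrow(wrep$missing), " missing cells, ",
         nrow(wrep$weight_sum), " weight-sum violations", call. = FALSE)
  }
  bk <- benchmark[c("country", "period", "age_group")]
  full_asfr <- lattice_cells(spec, by_education = FALSE)
  if (!all(cell_key(bk, names(bk)) %in% cell_key(full_asfr, names(bk)))) {
    stop("benchmark contains cells outside the lattice", call. = FALSE)
  }
  if (anyDuplicated(cell_key(bk, names(bk)))) {
    stop("benchmark has duplicated cells", call. = FALSE)
  }
  if (!is.null(prev_etfr) && nrow(prev_etfr)) {
    reg <- spec$region_assignment[prev_etfr$country]
    bad <- unique(prev_etfr$country[is.na(reg) |
                                      reg != "sub-Saharan Africa"])
    if (length(bad)) {
      stop("previously published ETFR supplied for non-sub-Saharan-African ",
           "countr(ies): ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(tau_asfr)) {
    v <- stats::var(benchmark$value)
    if (!is.finite(v) || v <= 0) {
      stop("cannot derive tau_asfr from a degenerate benchmark; supply it",
           call. = FALSE)
    }
    tau_asfr <- 1 / v
  }
  stopifnot(tau_asfr > 0, length(etfr_trunc) == 2,
            etfr_trunc[1] < etfr_trunc[2])
  structure(list(init = init, benchmark = benchmark, weights = weights,
                 prior_stats = prior_stats, prior_spec = prior_spec,
                 prev_etfr = prev_etfr, tau_asfr = tau_asfr,
                 etfr_trunc = etfr_trunc, spec = spec),
            class = "model_inputs")
}

#' Build the three-level hierarchical model
#'
#' Assembles the joint model over all countries and regions:
#' \itemize{
#'   \item Level 2: each EAFR is positive-truncated normal around its GLM
#'     center, with a per-cell precision drawn from the gamma prior of the
#'     chosen specification (or fixed, for oracle checks).
#'   \item Level 1: each observed benchmark ASFR is positive-truncated
#'     normal around the weight-aggregated EAFR with fixed precision
#'     `tau_asfr`; benchmark cells that are absent contribute no likelihood.
#'   \item Level 3: the ETFR estimate is truncated normal on (0, 10) around
#'     the derived ETFR (5 times the age sum), with a gamma precision prior
#'     built from the SD of the highest-education derived total rates; for
#'     sub-Saharan-African countries the previously published ETFR enters
#'     the same truncated-normal likelihood.
#' }
#'
#' @param inputs A [model_inputs()] object.
#' @param fix_tau_eafr Optional fixed per-cell EAFR precision (single value
#'   or vector in lattice order); when supplied the gamma prior on the EAFR
#'   precision is replaced by this constant (used by the conjugate oracle
#'   tests).
#' @return An object of class `fert_model`: the model text, the data list
#'   and bookkeeping needed by [run_mcmc()].
#' @export
build_model <- function(inputs, fix_tau_eafr = NULL) {
  stopifnot(inherits(inputs, "model_inputs"))
  spec <- inputs$spec
  E <- length(spec$education_levels); A <- length(spec$age_groups)
  Y <- length(spec$periods); C <- length(spec$countries)

  dhs <- align_to_lattice(inputs$init$predicted, spec, "GLM prediction grid")
  w <- align_to_lattice(inputs$weights, spec, "weight table")

  dat <- list(C = C, Y = Y, A = A, E = E,
              eafr_dhs = grid_to_array(pmax(dhs, 1e-8), spec),
              w = grid_to_array(w, spec),
              tau_asfr = inputs$tau_asfr)

  fixed_tau <- !is.null(fix_tau_eafr)
  if (fixed_tau) {
    dat$tau_eafr <- grid_to_array(rep_len(fix_tau_eafr, C * Y * A * E), spec)
  } else {
    pr <- instantiate_prior(inputs$prior_spec, inputs$prior_stats, spec)
    dat$tau_shape <- grid_to_array(pr$shape, spec)
    dat$tau_rate <- grid_to_array(pr$rate, spec)
  }

  bench <- inputs$benchmark
  K <- nrow(bench)
  if (K > 0) {
    dat$K <- K
    dat$ci <- match(bench$country, spec$countries)
    dat$yi <- match(bench$period, spec$periods)
    dat$ai <- match(bench$age_group, spec$age_groups)
    dat$asfr_un <- pmax(bench$value, 1e-8)
  }

  s_top <- inputs$prior_stats$sigma_etfr_e4
  if (!is.finite(s_top) || s_top <= 0) {
    stop("sd of highest-education derived ETFR is not positive; ",
         "ETFR precision prior cannot be built", call. = FALSE)
  }
  dat$etfr_shape <- 1 / s_top
  dat$etfr_rate <- 2 * s_top^2

  M <- if (is.null(inputs$prev_etfr)) 0L else nrow(inputs$prev_etfr)
  if (M > 0) {
    pe <- inputs$prev_etfr
    dat$M <- M
    dat$sci <- match(pe$country, spec$countries)
    dat$syi <- match(pe$period, spec$periods)
    dat$sei <- match(pe$education, spec$education_levels)
    dat$etfr_un <- pmin(pmax(pe$value, inputs$etfr_trunc[1] + 1e-6),
                        inputs$etfr_trunc[2] - 1e-6)
  }

  tb <- sprintf("T(%g,%g)", inputs$etfr_trunc[1], inputs$etfr_trunc[2])
  lines <- c(
    "model {",
    "  for (c in 1:C) { for (y in 1:Y) { for (a in 1:A) {",
    "    for (e in 1:E) {",
    "      eafr[c,y,a,e] ~ dnorm(eafr_dhs[c,y,a,e], tau_eafr[c,y,a,e]) T(0,)",
    if (!fixed_tau)
      "      tau_eafr[c,y,a,e] ~ dgamma(tau_shape[c,y,a,e], tau_rate[c,y,a,e])",
    "    }",
    "  }}}",
    if (K > 0) c(
      "  for (k in 1:K) {",
      "    asfr_un[k] ~ dnorm(inprod(eafr[ci[k],yi[k],ai[k],1:E],",
      "                              w[ci[k],yi[k],ai[k],1:E]), tau_asfr) T(0,)",
      "  }"),
    "  for (c in 1:C) { for (y in 1:Y) { for (e in 1:E) {",
    "    etfr_derived[c,y,e] <- 5 * sum(eafr[c,y,1:A,e])",
    paste0("    etfr_est[c,y,e] ~ dnorm(etfr_derived[c,y,e], ",
           "tau_etfr[c,y,e]) ", tb),
    "    tau_etfr[c,y,e] ~ dgamma(etfr_shape, etfr_rate)",
    "  }}}",
    if (M > 0) c(
      "  for (m in 1:M) {",
      paste0("    etfr_un[m] ~ dnorm(etfr_derived[sci[m],syi[m],sei[m]], ",
             "tau_etfr[sci[m],syi[m],sei[m]]) ", tb),
      "  }"),
    "}")

  structure(list(model_text = paste(lines, collapse = "\n"), data = dat,
                 spec = spec, fixed_tau = fixed_tau,
                 n_observed = K + M, n_benchmark_obs = K, n_ssa_obs = M,
                 etfr_trunc = inputs$etfr_trunc,
                 prior_spec = inputs$prior_spec$name),
            class = "fert_model")
}

#' @export
print.fert_model <- function(x, ...) {
  cat("<fert_model> prior '", x$prior_spec, "', ",
      prod(unlist(x$data[c("C", "Y", "A", "E")])), " EAFR cells, ",
      x$n_benchmark_obs, " benchmark + ", x$n_ssa_obs,
      " consistency observations\n", sep = "")
  invisible(x)
}

# split-half potential scale reduction, vectorized over parameters
split_rhat <- function(arr) {
  n <- dim(arr)[1]
  if (n %% 2 == 1) arr <- arr[-1, , , drop = FALSE]
  n2 <- dim(arr)[1] / 2
  halves <- list(arr[seq_len(n2), , , drop = FALSE],
                 arr[n2 + seq_len(n2), , , drop = FALSE])
  seq_means <- NULL; seq_vars <- NULL
  for (h in halves) {
    seq_means <- rbind(seq_means, apply(h, c(2, 3), mean))
    seq_vars <- rbind(seq_vars, apply(h, c(2, 3), stats::var))
  }
  W <- colMeans(seq_vars)
  B <- n2 * apply(seq_means, 2, stats::var)
  vp <- (n2 - 1) / n2 * W + B / n2
  out <- sqrt(vp / W)
  out[W == 0] <- 1
  out
}

# effective sample size with first-negative autocorrelation truncation,
# vectorized over parameters via FFT
ess_basic <- function(arr) {
  n <- dim(arr)[1]; m <- dim(arr)[2]; p <- dim(arr)[3]
  nf <- 2^ceiling(log2(2 * n))
  ac <- matrix(0, n, p)
  for (ch in seq_len(m)) {
    x <- scale(arr[, ch, , drop = TRUE], center = TRUE, scale = FALSE)
    x <- matrix(x, nrow = n)
    f <- stats::mvfft(rbind(x, matrix(0, nf - n, p)))
    ac <- ac + Re(stats::mvfft(f * Conj(f), inverse = TRUE))[seq_len(n), ,
                                                             drop = FALSE] / nf
  }
  rho <- sweep(ac, 2, ac[1, ], "/")
  rho[, ac[1, ] == 0] <- 0
  ess <- numeric(p)
  maxlag <- min(n - 1, 500)
  for (j in seq_len(p)) {
    r <- rho[-1, j][seq_len(maxlag)]
    cut <- which(r < 0)[1]
    s <- if (is.na(cut)) sum(r) else if (cut == 1) 0 else sum(r[seq_len(cut - 1)])
    ess[j] <- min(m * n, m * n / (1 + 2 * s))
  }
  ess
}

#' Run the MCMC sampler
#'
#' Samples the hierarchical model with JAGS, initializing the EAFR chains at
#' the GLM predictions. Draws are reproducible under `seed` (one RNG stream
#' per chain). Derived quantities -- the aggregated ASFR, the total rate and
#' the derived ETFR -- are computed from the EAFR draws in R, so the defining
#' identities hold exactly per draw. Split R-hat and effective sample size
#' are reported per monitored parameter; exceeding `rhat_threshold` attaches
#' a convergence warning, it is not fatal.
#'
#' @param model A [build_model()] result.
#' @param chains Number of chains (>= 2 for diagnostics).
#' @param warmup Burn-in iterations per chain (after adaptation).
#' @param iterations Retained iterations per chain.
#' @param seed Integer seed.
#' @param inits Optional initial EAFR values: a [fit_glm_init()] object or a
#'   vector in lattice order; defaults to the model's GLM centers.
#' @param adapt Adaptation iterations (default `min(500, warmup)`).
#' @param rhat_threshold Convergence warning threshold (default 1.05).
#' @return An object of class `fert_draws`.
#' @export
run_mcmc <- function(model, chains = 2, warmup = 500, iterations = 1000,
                     seed = 1L, inits = NULL, adapt = NULL,
                     rhat_threshold = 1.05) {
  stopifnot(inherits(model, "fert_model"), chains >= 1, iterations >= 2)
  spec <- model$spec
  E <- length(spec$education_levels); A <- length(spec$age_groups)
  Y <- length(spec$periods); C <- length(spec$countries)
  if (is.null(adapt)) adapt <- min(500, max(100, warmup))

  if (is.null(inits)) {
    eafr0 <- model$data$eafr_dhs
  } else if (inherits(inits, "glm_init")) {
    eafr0 <- grid_to_array(
      pmax(align_to_lattice(inits$predicted, spec, "inits"), 1e-6), spec)
  } else {
    eafr0 <- grid_to_array(pmax(rep_len(inits, C * Y * A * E), 1e-6), spec)
  }
  lo <- model$etfr_trunc[1]; hi <- model$etfr_trunc[2]
  etfr0 <- 5 * apply(eafr0, c(1, 2, 4), sum)
  etfr0 <- pmin(pmax(etfr0, lo + 1e-4), hi - 1e-4)
  init_list <- lapply(seq_len(chains), function(ch) {
    ini <- list(eafr = eafr0, etfr_est = etfr0,
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer(seed) + 1000L * ch)
    if (!model$fixed_tau) {
      ini$tau_eafr <- model$data$tau_shape / model$data$tau_rate
    }
    ini$tau_etfr <- array(model$data$etfr_shape / model$data$etfr_rate,
                          dim = c(C, Y, E))
    ini
  })

  jm <- rjags::jags.model(textConnection(model$model_text),
                          data = model$data, inits = init_list,
                          n.chains = chains, n.adapt = adapt, quiet = TRUE)
  if (warmup > 0) stats::update(jm, warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("eafr", "etfr_est"),
                              n.iter = iterations, progress.bar = "none")

  cells <- lattice_cells(spec)
  eafr_names <- sprintf("eafr[%d,%d,%d,%d]",
                        match(cells$country, spec$countries),
                        match(cells$period, spec$periods),
                        match(cells$age_group, spec$age_groups),
                        match(cells$education, spec$education_levels))
  etfr_cells <- lattice_cells(spec, by_age = FALSE)
  etfr_names <- sprintf("etfr_est[%d,%d,%d]",
                        match(etfr_cells$country, spec$countries),
                        match(etfr_cells$period, spec$periods),
                        match(etfr_cells$education, spec$education_levels))
  cn <- colnames(samp[[1]])
  ie <- match(eafr_names, cn)
  it <- match(etfr_names, cn)
  if (anyNA(ie) || anyNA(it)) {
    stop("internal error: monitored parameters missing from sampler output",
         call. = FALSE)
  }

  n <- iterations
  eafr_arr <- array(NA_real_, c(n, chains, length(ie)))
  etfr_arr <- array(NA_real_, c(n, chains, length(it)))
  for (ch in seq_len(chains)) {
    mm <- as.matrix(samp[[ch]])
    eafr_arr[, ch, ] <- mm[, ie]
    etfr_arr[, ch, ] <- mm[, it]
  }
  eafr_draws <- matrix(eafr_arr, nrow = n * chains)
  etfr_est_draws <- matrix(etfr_arr, nrow = n * chains)

  # derived quantities, exact per draw
  w <- align_to_lattice(model_weights_table(model), spec, "weights")
  Mw <- sweep(eafr_draws, 2, w, "*")
  ncell <- ncol(eafr_draws)
  asfr_draws <- 0
  for (e in seq_len(E)) {
    asfr_draws <- asfr_draws + Mw[, seq(e, ncell, by = E), drop = FALSE]
  }
  nasfr <- ncol(asfr_draws)
  tfr_draws <- 0
  for (a in seq_len(A)) {
    tfr_draws <- tfr_draws + asfr_draws[, seq(a, nasfr, by = A),
                                        drop = FALSE]
  }
  tfr_draws <- 5 * tfr_draws
  etfr_cells_idx <- expand.grid(e = seq_len(E), y = seq_len(Y),
                                c = seq_len(C))
  etfr_derived_draws <- 0
  for (a in seq_len(A)) {
    cols <- etfr_cells_idx$e + (a - 1) * E +
      ((etfr_cells_idx$y - 1) * A + (etfr_cells_idx$c - 1) * A * Y) * E
    etfr_derived_draws <- etfr_derived_draws +
      eafr_draws[, cols, drop = FALSE]
  }
  etfr_derived_draws <- 5 * etfr_derived_draws

  rhat <- c(split_rhat(eafr_arr), split_rhat(etfr_arr))
  ess <- c(ess_basic(eafr_arr), ess_basic(etfr_arr))
  names(rhat) <- names(ess) <- c(eafr_names, etfr_names)
  converged <- max(rhat) <= rhat_threshold
  if (!converged) {
    warning("convergence warning: max split R-hat ",
            signif(max(rhat), 4), " exceeds ", rhat_threshold,
            call. = FALSE)
  }

  structure(list(eafr = eafr_draws, asfr = asfr_draws, tfr = tfr_draws,
                 etfr_derived = etfr_derived_draws,
                 etfr_est = etfr_est_draws,
                 cells = list(eafr = cells,
                              asfr = lattice_cells(spec,
                                                   by_education = FALSE),
                              tfr = lattice_cells(spec, by_age = FALSE,
                                                  by_education = FALSE),
                              etfr = etfr_cells),
                 benchmark_uninformed = w == 0,
                 spec = spec, chains = chains, iterations = iterations,
                 warmup = warmup, seed = as.integer(seed),
                 rhat = rhat, ess = ess, converged = converged,
                 rhat_threshold = rhat_threshold,
                 prior_spec = model$prior_spec),
            class = "fert_draws")
}

# reconstruct the weights long table from the model data array
model_weights_table <- function(model) {
  spec <- model$spec
  grid <- lattice_cells(spec)
  grid$value <- as.vector(aperm(model$data$w, 4:1))
  grid
}

#' @export
print.fert_draws <- function(x, ...) {
  cat("<fert_draws> ", nrow(x$eafr), " draws (", x$chains, " chains x ",
      x$iterations, " iterations) over ", ncol(x$eafr),
      " EAFR cells; max R-hat ", signif(max(x$rhat), 4),
      if (!x$converged) " [convergence warning]", "\n", sep = "")
  invisible(x)
}

summary_table <- function(draws_mat, cells, level) {
  q <- apply(draws_mat, 2, stats::quantile,
             probs = c((1 - level) / 2, 0.5, 1 - (1 - level) / 2),
             names = FALSE)
  out <- cells
  out$median <- q[2, ]
  out$lower <- q[1, ]
  out$upper <- q[3, ]
  out$level <- level
  out
}

#' Posterior summaries
#'
#' Per-cell posterior median and central credible bounds for the EAFR, the
#' aggregated ASFR, the total rate and the ETFR estimates.
#'
#' @param draws A [run_mcmc()] result.
#' @param level Central interval probability (default 0.95).
#' @return An object of class `posterior_summary`: list of data frames
#'   `eafr`, `asfr`, `tfr`, `etfr`, each with `median`, `lower`, `upper`,
#'   `level`.
#' @export
summarize_draws <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "fert_draws"), level > 0, level < 1,
            nrow(draws$eafr) > 0)
  eafr_tab <- summary_table(draws$eafr, draws$cells$eafr, level)
  # zero-weight cells are estimated from the prior and Level 3 only
  eafr_tab$benchmark_uninformed <- draws$benchmark_uninformed
  structure(list(eafr = eafr_tab,
                 asfr = summary_table(draws$asfr, draws$cells$asfr, level),
                 tfr = summary_table(draws$tfr, draws$cells$tfr, level),
                 etfr = summary_table(draws$etfr_est, draws$cells$etfr,
                                      level),
                 level = level),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary> level ", x$level, "; ", nrow(x$eafr),
      " EAFR cells, ", nrow(x$asfr), " ASFR cells, ", nrow(x$tfr),
      " TFR cells, ", nrow(x$etfr), " ETFR cells\n", sep = "")
  invisible(x)
}
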