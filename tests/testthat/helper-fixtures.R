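# Shared fixtures, computed once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small world: 3 countries (2 sub-Saharan African), 6 periods -> 504 cells
tiny_config <- function(seed = 11L, ...) {
  world_config(
    region_assignment = c(CountryA = "sub-Saharan Africa",
                          CountryB = "sub-Saharan Africa",
                          CountryC = "Latin America"),
    periods = fert_periods(1990, 2015),
    survey_years = list(CountryA = c(1998, 2010, 2021),
                        CountryB = c(2004, 2016),
                        CountryC = c(1995, 2007, 2019)),
    seed = seed, ...)
}

tiny_world <- function() fixture("tiny_world", simulate_world(tiny_config()))

tiny_inputs <- function() {
  fixture("tiny_inputs", {
    w <- tiny_world()
    spec <- world_lattice(w$config)
    init <- fit_glm_init(clean_observations(w$surveys), spec)
    model_inputs(init, w$benchmark, w$weights,
                 derive_prior_statistics(init), prev_etfr = w$prev_etfr)
  })
}

tiny_fit <- function() {
  fixture("tiny_fit", {
    run_mcmc(build_model(tiny_inputs()), chains = 2, warmup = 300,
             iterations = 400, seed = 99)
  })
}

# desk-scale apparatus: default world, GLM initialization, and a companion
# world drawn from the fitted model's own generative process
default_apparatus <- function() {
  fixture("default_apparatus", {
    w <- simulate_world(world_config())
    spec <- world_lattice(w$config)
    init <- fit_glm_init(clean_observations(w$surveys), spec)
    stats <- derive_prior_statistics(init)
    inputs <- model_inputs(init, w$benchmark, w$weights, stats,
                           prev_etfr = w$prev_etfr)
    sbc <- simulate_from_model(inputs, seed = 101)
    sbc_inputs <- model_inputs(init, sbc$benchmark, w$weights, stats,
                               prev_etfr = NULL)
    list(world = w, spec = spec, init = init, stats = stats,
         inputs = inputs, sbc = sbc, sbc_inputs = sbc_inputs)
  })
}

# posterior-median ASFR error against a benchmark, and the same error for
# the weight-aggregated GLM initial values
asfr_rmse_pair <- function(fit, init, weights, benchmark) {
  k <- edufert:::cell_key(benchmark, c("country", "period", "age_group"))
  med <- apply(fit$asfr, 2, stats::median)
  pos <- match(k, edufert:::cell_key(fit$cells$asfr,
                                     c("country", "period", "age_group")))
  wv <- weights$value[match(edufert:::cell_key(init$predicted),
                            edufert:::cell_key(weights))]
  kk <- edufert:::cell_key(init$predicted,
                           c("country", "period", "age_group"))
  agg <- rowsum(init$predicted$value * wv, kk)
  glm_agg <- agg[match(unique(kk), rownames(agg)), 1][match(k, unique(kk))]
  c(posterior = sqrt(mean((med[pos] - benchmark$value)^2)),
    glm = sqrt(mean((glm_agg - benchmark$value)^2)))
}

# hand-built prior statistics for oracle models on hand-built lattices
fake_prior_statistics <- function(spec, sigma = 0.05, mu = 0.05,
                                  sigma_etfr = 0.5) {
  e <- spec$education_levels
  a <- spec$age_groups
  structure(list(
    sigma_e = stats::setNames(rep(sigma, length(e)), e),
    mu_e = stats::setNames(rep(mu, length(e)), e),
    sigma2_e = stats::setNames(rep(sigma^2, length(e)), e),
    sigma_pooled = sigma, sigma2_pooled = sigma^2, mu_pooled = mu,
    var_mean_ratio = sigma^2 / mu, sigma2_est = 0.01,
    sigma_ae = matrix(sigma, length(a), length(e),
                      dimnames = list(a, e)),
    sigma_etfr_e4 = sigma_etfr,
    education_levels = e, age_groups = a),
    class = "prior_statistics")
}

# single country/period/age lattice with degenerate weights (1,0,0,0)
single_cell_setup <- function(m0 = 0.25, b = 0.20, sd0 = 0.04, sd1 = 0.03) {
  spec <- lattice_spec(countries = "CountryA", periods = "2000-2005",
                       age_groups = "25-29",
                       region_assignment = c(CountryA = "Latin America"))
  grid <- lattice_cells(spec)
  pred <- grid; pred$value <- m0
  se <- grid; se$value <- sd0
  init <- as_glm_init(pred, se, spec)
  weights <- grid
  weights$value <- c(1, 0, 0, 0)
  bench <- data.frame(country = "CountryA", period = "2000-2005",
                      age_group = "25-29", value = b)
  inputs <- model_inputs(init, bench, weights,
                         fake_prior_statistics(spec),
                         tau_asfr = 1 / sd1^2)
  list(spec = spec, inputs = inputs, m0 = m0, b = b, sd0 = sd0, sd1 = sd1)
}

# numerical-quadrature posterior for the single-cell model: positive-
# truncated normal prior around m0, benchmark likelihood positive-truncated
# normal around the parameter (its normalizer depends on the parameter)
quadrature_posterior <- function(m0, b, sd0, sd1) {
  dens <- function(x) {
    stats::dnorm(x, m0, sd0) * stats::dnorm(b, x, sd1) /
      stats::pnorm(x / sd1)
  }
  z <- stats::integrate(dens, 0, Inf, rel.tol = 1e-10)$value
  m1 <- stats::integrate(function(x) x * dens(x), 0, Inf,
                         rel.tol = 1e-10)$value / z
  m2 <- stats::integrate(function(x) x^2 * dens(x), 0, Inf,
                         rel.tol = 1e-10)$value / z
  list(mean = m1, sd = sqrt(m2 - m1^2))
}

# minimal draws object for summary/coverage oracles
fake_draws <- function(asfr, cells_asfr) {
  n <- nrow(asfr)
  structure(list(
    eafr = asfr, asfr = asfr, tfr = asfr, etfr_derived = asfr,
    etfr_est = asfr,
    cells = list(eafr = cbind(cells_asfr, education = "No Education"),
                 asfr = cells_asfr,
                 tfr = cells_asfr[c("country", "period")],
                 etfr = cbind(cells_asfr[c("country", "period")],
                              education = "No Education")),
    benchmark_uninformed = rep(FALSE, ncol(asfr)),
    spec = NULL, chains = 1, iterations = n, warmup = 0, seed = 1L,
    rhat = rep(1, ncol(asfr)), ess = rep(n, ncol(asfr)),
    converged = TRUE, rhat_threshold = 1.05, prior_spec = "final"),
    class = "fert_draws")
}

# YAML configuration for command-line pipeline tests
cli_config <- function(workdir, iterations = 150) {
  cfg <- list(
    workdir = workdir,
    world = list(
      region_assignment = list(CountryA = "sub-Saharan Africa",
                               CountryB = "sub-Saharan Africa",
                               CountryC = "Latin America"),
      periods = fert_periods(1995, 2015),
      survey_years = list(CountryA = c(1998, 2010, 2021),
                          CountryB = c(2004, 2016),
                          CountryC = c(1995, 2007, 2019)),
      seed = 11),
    mcmc = list(chains = 2, warmup = 100, iterations = iterations,
                seed = 3),
    prior_spec = "final",
    holdout = list(fractions = c(0.1), seed = 5),
    levels = c(0.5, 0.8, 0.9))
  path <- file.path(workdir, "config.yaml")
  yaml::write_yaml(cfg, path)
  path
}
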