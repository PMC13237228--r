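#' Configuration for a synthetic fertility world
#'
#' Defines the ground-truth fertility surface and the observation processes
#' emulating the three input streams of the estimation pipeline: survey-derived
#' education- and age-specific rates with a 30-year recall window, a harmonized
#' age-specific benchmark schedule, and education-composition weights of the
#' female population. Optionally a fourth stream of previously published
#' education-specific total fertility rates for sub-Saharan African countries.
#'
#' The defaults describe a desk-scale world: six countries spanning four
#' regions (two in sub-Saharan Africa), ten five-year periods from 1970-1975
#' to 2015-2020, seven age groups and four education levels (1,680 cells).
#'
#' @param n_countries Number of countries.
#' @param region_assignment Named character vector country -> region, regions
#'   drawn from [fert_regions()].
#' @param periods Ordered five-year period labels.
#' @param age_groups Seven five-year age-group labels.
#' @param education_levels Four education labels.
#' @param base_level Named numeric: peak fertility rate scale per region
#'   (births per woman per year).
#' @param education_gradient Named numeric, one multiplicative level factor
#'   per education level (non-increasing by default: higher attainment, lower
#'   fertility).
#' @param decline_rate Per-period log-linear decline of the rate level.
#' @param postponement_shift Named numeric, peak-age shift in years per
#'   education level (non-decreasing by default: higher attainment, later
#'   childbearing).
#' @param survey_years Named list country -> integer survey calendar years.
#' @param recall_window Years of birth history covered before a survey.
#' @param exposure_scale Person-years of exposure per fully weighted cell.
#' @param benchmark_noise_sd SD of the positive-truncated Gaussian
#'   perturbation applied to the emulated benchmark ASFR.
#' @param prev_etfr_noise_sd SD of the perturbation applied to the emulated
#'   previously published sub-Saharan-African ETFR.
#' @param seed Integer seed governing all randomness of the world.
#' @return An object of class `world_config`.
#' @export
world_config <- function(n_countries = 6,
                         region_assignment = NULL,
                         periods = fert_periods(1970, 2015),
                         age_groups = fert_age_groups(),
                         education_levels = fert_education_levels(),
                         base_level = NULL,
                         education_gradient = NULL,
                         decline_rate = 0.04,
                         postponement_shift = NULL,
                         survey_years = NULL,
                         recall_window = 30,
                         exposure_scale = 2000,
                         benchmark_noise_sd = 0.005,
                         prev_etfr_noise_sd = 0.1,
                         seed = 1L) {
  if (is.null(region_assignment)) {
    countries <- paste0("Country", LETTERS[seq_len(n_countries)])
    default_regions <- c("sub-Saharan Africa", "sub-Saharan Africa",
                         "North Africa", "South & Southeast Asia",
                         "Latin America", "Europe")
    region_assignment <- stats::setNames(
      rep_len(default_regions, n_countries), countries)
  }
  countries <- names(region_assignment)
  if (is.null(base_level)) {
    base_level <- c("sub-Saharan Africa" = 0.32, "North Africa" = 0.26,
                    "West Asia" = 0.25, "Europe" = 0.16,
                    "Central Asia" = 0.22, "South & Southeast Asia" = 0.24,
                    "Latin America" = 0.24)
  }
  if (is.null(education_gradient)) {
    education_gradient <- stats::setNames(
      c(1.0, 0.95, 0.70, 0.50)[seq_along(education_levels)],
      education_levels)
  }
  if (is.null(postponement_shift)) {
    postponement_shift <- stats::setNames(
      c(0, 0.5, 2, 4)[seq_along(education_levels)], education_levels)
  }
  if (is.null(survey_years)) {
    waves <- list(c(1986, 1998, 2010, 2022), c(1992, 2004, 2016),
                  c(1995, 2007, 2019), c(1990, 2003, 2015),
                  c(1988, 2000, 2013), c(1999, 2011, 2023))
    survey_years <- stats::setNames(
      rep_len(waves, length(countries)), countries)
  }

  cfg <- structure(
    list(n_countries = length(countries),
         region_assignment = region_assignment,
         periods = periods, age_groups = age_groups,
         education_levels = education_levels,
         base_level = base_level,
         education_gradient = education_gradient,
         decline_rate = decline_rate,
         postponement_shift = postponement_shift,
         survey_years = survey_years,
         recall_window = recall_window,
         exposure_scale = exposure_scale,
         benchmark_noise_sd = benchmark_noise_sd,
         prev_etfr_noise_sd = prev_etfr_noise_sd,
         seed = as.integer(seed)),
    class = "world_config")
  validate_world_config(cfg)
  cfg
}

validate_world_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid world_config: field '", field, "' ", why, call. = FALSE)
  }
  if (length(cfg$age_groups) != 7) fail("age_groups", "must have 7 entries")
  if (length(cfg$education_levels) < 1) fail("education_levels", "is empty")
  check_period_labels(cfg$periods)
  bad_region <- setdiff(unique(cfg$region_assignment), fert_regions())
  if (length(bad_region)) {
    fail("region_assignment",
         paste0("uses unknown region(s): ", paste(bad_region, collapse = ", ")))
  }
  for (f in c("base_level", "education_gradient")) {
    if (any(!is.finite(cfg[[f]])) || any(cfg[[f]] <= 0)) {
      fail(f, "must be strictly positive")
    }
  }
  if (!setequal(names(cfg$education_gradient), cfg$education_levels)) {
    fail("education_gradient", "must be named by every education level")
  }
  if (!setequal(names(cfg$postponement_shift), cfg$education_levels)) {
    fail("postponement_shift", "must be named by every education level")
  }
  if (!all(unique(cfg$region_assignment) %in% names(cfg$base_level))) {
    fail("base_level", "must cover every assigned region")
  }
  if (cfg$recall_window <= 0) fail("recall_window", "must be positive")
  if (cfg$exposure_scale <= 0) fail("exposure_scale", "must be positive")
  if (cfg$benchmark_noise_sd < 0) fail("benchmark_noise_sd", "must be >= 0")
  if (cfg$prev_etfr_noise_sd < 0) fail("prev_etfr_noise_sd", "must be >= 0")
  invisible(cfg)
}

#' @export
print.world_config <- function(x, ...) {
  cat("<world_config> ", x$n_countries, " countries, ",
      length(x$periods), " periods, ", length(x$age_groups), " ages, ",
      length(x$education_levels), " educations; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Lattice specification of a world
#' @param config A [world_config()].
#' @return The corresponding [lattice_spec()].
#' @export
world_lattice <- function(config) {
  lattice_spec(countries = names(config$region_assignment),
               periods = config$periods,
               age_groups = config$age_groups,
               education_levels = config$education_levels,
               region_assignment = config$region_assignment)
}

#' Ground-truth education- and age-specific fertility schedules
#'
#' Builds the complete EAFR lattice from a gamma-density-shaped age curve over
#' age-group midpoints: within each country the schedule is scaled by the
#' region's base level and the education gradient, its peak age is shifted by
#' the education-specific postponement, and the level declines log-linearly
#' across periods. All rates are strictly positive.
#'
#' @param config A [world_config()].
#' @return A rate grid: data frame `country`, `region`, `period`, `age_group`,
#'   `education`, `value` over the complete lattice.
#' @export
generate_true_schedules <- function(config) {
  validate_world_config(config)
  spec <- world_lattice(config)
  grid <- lattice_cells(spec)
  grid$region <- unname(config$region_assignment[grid$country])

  mid <- age_mid(grid$age_group)
  shift <- unname(config$postponement_shift[grid$education])
  peak <- 27 + shift
  shape <- 4.5
  # gamma density over (age - 12) with mode at the peak age, normalized so
  # the maximum over the seven midpoints is 1 for each education curve
  curve_at <- function(age, pk) {
    rate <- (shape - 1) / (pk - 12)
    stats::dgamma(age - 12, shape = shape, rate = rate)
  }
  raw <- curve_at(mid, peak)
  mids <- age_mid(config$age_groups)
  peak_max <- vapply(config$postponement_shift, function(s) {
    max(curve_at(mids, 27 + s))
  }, numeric(1))
  raw <- raw / unname(peak_max[grid$education])

  t_idx <- match(grid$period, config$periods) - 1
  level <- unname(config$base_level[grid$region]) *
    unname(config$education_gradient[grid$education]) *
    exp(-config$decline_rate * t_idx)
  grid$value <- pmax(level * raw, 1e-8)
  grid[c("country", "region", "period", "age_group", "education", "value")]
}

#' Education-composition weights of the female population
#'
#' Emulates population shares by education within each country-period-age
#' cell: the no-education share contracts and the secondary/higher shares
#' expand over periods (education expansion); higher education has weight 0
#' at ages 15-19 and secondary is reduced there. Shares are renormalized to
#' sum to exactly 1 within each (country, period, age) cell.
#'
#' @param config A [world_config()].
#' @return Weight table: data frame `country`, `period`, `age_group`,
#'   `education`, `value` with per-cell weight sums of 1.
#' @export
generate_weights <- function(config) {
  validate_world_config(config)
  spec <- world_lattice(config)
  grid <- lattice_cells(spec)
  t_idx <- match(grid$period, config$periods) - 1

  ne <- length(config$education_levels)
  base_raw <- c(1.5, 1.2, 0.5, 0.15)[seq_len(ne)]
  growth <- c(-0.08, 0, 0.10, 0.12)[seq_len(ne)]
  e_idx <- match(grid$education, config$education_levels)
  raw <- base_raw[e_idx] * exp(growth[e_idx] * t_idx)

  youngest <- grid$age_group == config$age_groups[1]
  if (ne >= 4) raw[youngest & e_idx == 4] <- 0
  if (ne >= 3) raw[youngest & e_idx == 3] <- raw[youngest & e_idx == 3] * 0.5

  key <- cell_key(grid, c("country", "period", "age_group"))
  grid$value <- normalize_cell_shares(raw, key)
  grid[c("country", "period", "age_group", "education", "value")]
}

# renormalize raw population shares to sum to 1 within each cell
normalize_cell_shares <- function(raw, key) {
  raw / stats::ave(raw, key, FUN = sum)
}

positive_truncated_noise <- function(mean, sd) {
  if (sd == 0) return(mean)
  out <- mean + stats::rnorm(length(mean), 0, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- mean[bad] + stats::rnorm(length(bad), 0, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Emulated benchmark ASFR table
#'
#' Aggregates the ground-truth EAFR with the education weights to the
#' age-specific marginal and perturbs it with positive-truncated Gaussian
#' noise, emulating a harmonized benchmark schedule consistent with the
#' weighted truth.
#'
#' @param truth Rate grid from [generate_true_schedules()].
#' @param weights Weight table from [generate_weights()] on the same lattice.
#' @param noise_sd Perturbation SD (0 gives exact weighted aggregation).
#' @param seed Integer seed.
#' @return Benchmark table: data frame `country`, `period`, `age_group`,
#'   `value` with attribute `provenance = "primary"`.
#' @export
generate_benchmark <- function(truth, weights, noise_sd = 0, seed = 1L) {
  tk <- cell_key(truth)
  wk <- cell_key(weights)
  missing <- setdiff(tk, wk)
  extra <- setdiff(wk, tk)
  if (length(missing) || length(extra)) {
    stop("truth and weights are not on the same lattice; e.g. cells ",
         paste(utils::head(gsub("\r", "/", c(missing, extra)), 3),
               collapse = ", "), call. = FALSE)
  }
  w <- weights$value[match(tk, wk)]
  key <- cell_key(truth, c("country", "period", "age_group"))
  agg <- rowsum(truth$value * w, key)
  cells <- truth[!duplicated(key), c("country", "period", "age_group")]
  cells$value <- agg[match(unique(key), rownames(agg)), 1]
  rownames(cells) <- NULL
  withr_seed(seed, {
    cells$value <- positive_truncated_noise(cells$value, noise_sd)
  })
  attr(cells, "provenance") <- "primary"
  cells
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Emulated survey observations of education-specific fertility
#'
#' For each survey wave of each country, observes the ground-truth EAFR over
#' the recall window before the survey: birth counts are Poisson draws given
#' person-years of exposure, and the recorded rate is births/exposure.
#' Exposure scales with the education-composition weight, so rare
#' education-age combinations yield missing or zero cells; age groups whose
#' cohort would have aged beyond the reproductive span by the survey date are
#' unobservable, producing the truncated age schedules the GLM step completes.
#'
#' @param truth Rate grid from [generate_true_schedules()].
#' @param config The [world_config()] (supplies survey years, recall window,
#'   exposure scale and weights).
#' @param weights Optional weight table; regenerated from `config` if omitted.
#' @param seed Integer seed.
#' @param min_exposure Cells with fewer person-years than this are dropped.
#' @return Survey observation table: data frame `country`, `region`,
#'   `period`, `age_group`, `education`, `value`, `births`, `exposure`,
#'   `survey_year`.
#' @export
generate_surveys <- function(truth, config, weights = NULL, seed = 1L,
                             min_exposure = 0.5) {
  validate_world_config(config)
  if (is.null(weights)) weights <- generate_weights(config)
  wk <- cell_key(weights)
  rows <- vector("list", 0)
  withr_seed(seed, {
    for (ctry in names(config$region_assignment)) {
      yrs <- config$survey_years[[ctry]]
      if (is.null(yrs) || !length(yrs)) {
        warning("country ", ctry, " has no survey waves; ",
                "it contributes no observations", call. = FALSE)
        next
      }
      base <- truth[truth$country == ctry, , drop = FALSE]
      for (sy in sort(yrs)) {
        start <- period_start(base$period)
        in_window <- start < sy & start >= sy - config$recall_window
        # cohort observability: women in this age group at this period must
        # still be of reproductive age at the survey date
        observable <- age_mid(base$age_group) + (sy - period_mid(base$period)) <=
          age_mid(config$age_groups[length(config$age_groups)])
        obs <- base[in_window & observable, , drop = FALSE]
        if (!nrow(obs)) next
        w <- weights$value[match(cell_key(obs), wk)]
        exposure <- config$exposure_scale * w
        keep <- exposure >= min_exposure
        obs <- obs[keep, , drop = FALSE]
        exposure <- exposure[keep]
        births <- stats::rpois(nrow(obs), exposure * obs$value)
        obs$value <- births / exposure
        obs$births <- births
        obs$exposure <- exposure
        obs$survey_year <- sy
        rows[[length(rows) + 1]] <- obs
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Emulated previously published education-specific TFR for sub-Saharan Africa
#'
#' Derives the true education-specific total fertility rate (5 times the age
#' sum of the EAFR) for the requested sub-Saharan African countries and
#' perturbs it with positive-truncated noise, emulating earlier published
#' estimates that the hierarchical model uses as a consistency anchor.
#'
#' @param truth Rate grid from [generate_true_schedules()] (must carry a
#'   `region` column).
#' @param ssa_countries Countries to include; must all be assigned to
#'   sub-Saharan Africa.
#' @param noise_sd Perturbation SD.
#' @param seed Integer seed.
#' @return Data frame `country`, `period`, `education`, `value` (ETFR).
#' @export
generate_prev_etfr <- function(truth, ssa_countries, noise_sd = 0, seed = 1L) {
  if (!length(ssa_countries)) {
    return(data.frame(country = character(), period = character(),
                      education = character(), value = numeric()))
  }
  reg <- unique(truth[c("country", "region")])
  bad <- ssa_countries[!(ssa_countries %in% reg$country) |
    reg$region[match(ssa_countries, reg$country)] != "sub-Saharan Africa"]
  if (length(bad)) {
    stop("not sub-Saharan African countries: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sub <- truth[truth$country %in% ssa_countries, , drop = FALSE]
  key <- cell_key(sub, c("country", "period", "education"))
  agg <- rowsum(sub$value, key)
  out <- sub[!duplicated(key), c("country", "period", "education")]
  out$value <- 5 * agg[match(unique(key), rownames(agg)), 1]
  rownames(out) <- NULL
  withr_seed(seed, {
    out$value <- positive_truncated_noise(out$value, noise_sd)
  })
  out
}

#' Generate a complete synthetic world
#'
#' Orchestrates the ground truth and all four emulated input streams under a
#' single root seed (sub-seeds are derived per stream, so each stream is
#' individually reproducible).
#'
#' @param config A [world_config()].
#' @return An object of class `synthetic_world`: list with elements `truth`,
#'   `weights`, `benchmark`, `surveys`, `prev_etfr`, `config`.
#' @export
simulate_world <- function(config = world_config()) {
  validate_world_config(config)
  truth <- generate_true_schedules(config)
  weights <- generate_weights(config)
  benchmark <- generate_benchmark(truth, weights,
                                  noise_sd = config$benchmark_noise_sd,
                                  seed = config$seed + 1L)
  surveys <- generate_surveys(truth, config, weights = weights,
                              seed = config$seed + 2L)
  ssa <- names(config$region_assignment)[
    config$region_assignment == "sub-Saharan Africa"]
  prev_etfr <- generate_prev_etfr(truth, ssa,
                                  noise_sd = config$prev_etfr_noise_sd,
                                  seed = config$seed + 3L)
  structure(list(truth = truth, weights = weights, benchmark = benchmark,
                 surveys = surveys, prev_etfr = prev_etfr, config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> ", nrow(x$truth), " true cells, ",
      nrow(x$surveys), " survey rows, ", nrow(x$benchmark),
      " benchmark rows, ", nrow(x$prev_etfr), " prior-ETFR rows\n", sep = "")
  invisible(x)
}

#' Write the streams of a synthetic world as long-format CSV
#'
#' @param world A [simulate_world()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(truth = file.path(dir, "truth.csv"),
             weights = file.path(dir, "weights.csv"),
             benchmark = file.path(dir, "benchmark.csv"),
             surveys = file.path(dir, "surveys.csv"),
             prev_etfr = file.path(dir, "prev_etfr.csv"))
  write_long_csv(world$truth, paths["truth"])
  write_long_csv(world$weights, paths["weights"])
  write_long_csv(world$benchmark, paths["benchmark"])
  write_long_csv(world$surveys, paths["surveys"])
  write_long_csv(world$prev_etfr, paths["prev_etfr"])
  invisible(paths)
}
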