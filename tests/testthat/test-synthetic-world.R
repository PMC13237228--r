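test_that("true schedules collapse to a single curve in the identity case", {
  edu <- fert_education_levels()
  cfg <- world_config(
    education_gradient = stats::setNames(rep(1, 4), edu),
    postponement_shift = stats::setNames(rep(0, 4), edu),
    decline_rate = 0)
  truth <- generate_true_schedules(cfg)
  # all education levels and all periods share one age schedule per country
  base <- truth[truth$education == edu[1] &
                  truth$period == cfg$periods[1], ]
  for (e in edu) {
    for (p in cfg$periods) {
      slice <- truth[truth$education == e & truth$period == p, ]
      expect_equal(slice$value[match(paste(base$country, base$age_group),
                                     paste(slice$country,
                                           slice$age_group))],
                   base$value, tolerance = 1e-12)
    }
  }
})

test_that("the lattice uses the four attainment labels and ten periods", {
  truth <- generate_true_schedules(world_config())
  expect_setequal(unique(truth$education),
                  c("No Education", "Primary Education",
                    "Secondary Education", "Higher Education"))
  per_country <- table(truth$country, truth$period)
  expect_true(all(per_country == 28))          # 7 ages x 4 educations
  expect_identical(ncol(per_country), 10L)     # 1970-1975 ... 2015-2020
  expect_true(all(truth$value > 0))
})

test_that("schedules encode gradient, postponement and log-linear decline", {
  cfg <- world_config()
  truth <- generate_true_schedules(cfg)
  one <- truth[truth$country == "CountryA" & truth$period == "1990-1995", ]
  no_ed <- one$value[one$education == "No Education"]
  hi_ed <- one$value[one$education == "Higher Education"]
  ages <- unique(one$age_group)
  expect_lt(max(hi_ed), max(no_ed))                      # lower level
  expect_gt(match(ages[which.max(hi_ed)], ages),
            match(ages[which.max(no_ed)], ages) - 1)     # later-or-equal peak
  expect_gt(sum(hi_ed) / 7, 0)
  # log-linear decline at decline_rate between consecutive periods
  a <- truth[truth$country == "CountryA" & truth$age_group == "25-29" &
               truth$education == "No Education", ]
  a <- a[match(cfg$periods, a$period), ]
  expect_equal(diff(log(a$value)),
               rep(-cfg$decline_rate, length(cfg$periods) - 1),
               tolerance = 1e-9)
})

test_that("invalid configurations name the offending field", {
  expect_error(world_config(decline_rate = 0.02, exposure_scale = -5),
               "exposure_scale")
  expect_error(world_config(age_groups = c("15-19", "20-24")),
               "age_groups")
  expect_error(world_config(region_assignment = c(X = "Mars")), "region")
})

test_that("weights are normalized and a single level degenerates to 1", {
  w <- generate_weights(world_config())
  key <- edufert:::cell_key(w, c("country", "period", "age_group"))
  sums <- rowsum(w$value, key)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(w$value >= 0 & w$value <= 1))
  # higher education has zero weight in the youngest age group
  expect_true(all(w$value[w$age_group == "15-19" &
                            w$education == "Higher Education"] == 0))

  cfg1 <- world_config(education_levels = "No Education")
  w1 <- generate_weights(cfg1)
  expect_true(all(w1$value == 1))
})

test_that("raw shares renormalize by direct arithmetic", {
  expect_equal(edufert:::normalize_cell_shares(c(2, 1, 1, 0),
                                               rep("cell", 4)),
               c(0.5, 0.25, 0.25, 0))
})

test_that("higher-education share expands across periods", {
  cfg <- world_config()
  w <- generate_weights(cfg)
  hi <- w[w$education == "Higher Education" & w$age_group == "30-34" &
            w$country == "CountryA", ]
  hi <- hi$value[match(cfg$periods, hi$period)]
  expect_true(all(diff(hi) >= 0))
})

test_that("benchmark equals the weighted truth without noise", {
  cfg <- world_config()
  truth <- generate_true_schedules(cfg)
  w <- generate_weights(cfg)
  b <- generate_benchmark(truth, w, noise_sd = 0, seed = 5)
  key <- edufert:::cell_key(truth, c("country", "period", "age_group"))
  agg <- rowsum(truth$value * w$value[match(edufert:::cell_key(truth),
                                            edufert:::cell_key(w))],
                key)
  expect_equal(b$value, agg[match(unique(key), rownames(agg)), 1],
               ignore_attr = TRUE, tolerance = 1e-12)

  cell <- data.frame(country = "X", period = "2000-2005",
                     age_group = "25-29",
                     education = fert_education_levels(),
                     value = c(0.30, 0.25, 0.15, 0.10))
  wcell <- cell
  wcell$value <- c(0.5, 0.3, 0.15, 0.05)
  expect_equal(generate_benchmark(cell, wcell, 0, 1)$value, 0.2525)

  # equal rates across educations: the convex combination returns that rate
  eq <- cell; eq$value <- 0.2
  expect_equal(generate_benchmark(eq, wcell, 0, 1)$value, 0.2)
})

test_that("benchmark generation is reproducible and lattice-checked", {
  cfg <- world_config()
  truth <- generate_true_schedules(cfg)
  w <- generate_weights(cfg)
  b1 <- generate_benchmark(truth, w, noise_sd = 0.01, seed = 3)
  b2 <- generate_benchmark(truth, w, noise_sd = 0.01, seed = 3)
  expect_identical(b1, b2)
  expect_true(all(b1$value > 0))
  expect_error(generate_benchmark(truth[-1, ], w, 0, 1), "lattice")
})

test_that("survey observations respect the recall window and cohort ages", {
  cfg <- world_config(
    region_assignment = c(CountryA = "sub-Saharan Africa"),
    periods = fert_periods(1955, 1990),
    survey_years = list(CountryA = 1995))
  truth <- generate_true_schedules(cfg)
  s <- generate_surveys(truth, cfg, seed = 2)
  expect_false(any(s$period %in% c("1955-1960", "1960-1965")))
  expect_true(all(s$period %in% fert_periods(1965, 1990)))
  # distant periods lose their oldest age groups (cohort truncation)
  expect_false("45-49" %in% s$age_group[s$period == "1965-1970"])
})

test_that("multiple waves observe overlapping periods repeatedly", {
  s <- tiny_world()$surveys
  key <- edufert:::cell_key(s)
  expect_gt(sum(duplicated(key)), 0)
  waves <- unique(s[c("country", "survey_year")])
  expect_gt(nrow(waves), length(unique(s$country)))
})

test_that("observed rates converge to the truth at large exposure", {
  cfg <- world_config(
    region_assignment = c(CountryA = "sub-Saharan Africa"),
    periods = fert_periods(2000, 2015),
    survey_years = list(CountryA = 2020),
    exposure_scale = 1e7)
  truth <- generate_true_schedules(cfg)
  s <- generate_surveys(truth, cfg, seed = 8)
  tv <- truth$value[match(edufert:::cell_key(s), edufert:::cell_key(truth))]
  big <- s$exposure * tv >= 1e4
  expect_gt(sum(big), 50)
  expect_lt(max(abs(s$value[big] - tv[big]) / tv[big]), 0.01)
})

test_that("countries without surveys warn and contribute nothing", {
  cfg <- tiny_config()
  cfg$survey_years$CountryC <- NULL
  truth <- generate_true_schedules(cfg)
  expect_warning(s <- generate_surveys(truth, cfg, seed = 2), "CountryC")
  expect_false("CountryC" %in% s$country)
})

test_that("previously published ETFR derives from the truth", {
  cfg <- tiny_config()
  truth <- generate_true_schedules(cfg)
  pe <- generate_prev_etfr(truth, c("CountryA", "CountryB"), noise_sd = 0,
                           seed = 4)
  sub <- truth[truth$country == "CountryA" &
                 truth$period == "1990-1995" &
                 truth$education == "No Education", ]
  expect_equal(pe$value[pe$country == "CountryA" &
                          pe$period == "1990-1995" &
                          pe$education == "No Education"],
               5 * sum(sub$value), tolerance = 1e-12)

  flat <- truth[truth$country %in% c("CountryA", "CountryB"), ]
  flat$value <- 0.1
  pf <- generate_prev_etfr(flat, "CountryA", 0, 1)
  expect_true(all(abs(pf$value - 3.5) < 1e-12))

  expect_identical(nrow(generate_prev_etfr(truth, character(0), 0, 1)), 0L)
  expect_error(generate_prev_etfr(truth, "CountryC", 0, 1),
               "sub-Saharan")
})

test_that("a world is deterministic under its seed and internally consistent", {
  w1 <- simulate_world(tiny_config())
  w2 <- simulate_world(tiny_config())
  expect_identical(w1, w2)
  # benchmark consistency at the configured noise level
  key <- edufert:::cell_key(w1$truth, c("country", "period", "age_group"))
  agg <- rowsum(
    w1$truth$value * w1$weights$value[match(edufert:::cell_key(w1$truth),
                                            edufert:::cell_key(w1$weights))],
    key)
  resid <- w1$benchmark$value - agg[match(unique(key), rownames(agg)), 1]
  expect_lt(max(abs(resid)), 5 * w1$config$benchmark_noise_sd)
})

test_that("mean ETFR is ordered by education in every period", {
  w <- tiny_world()
  key <- edufert:::cell_key(w$truth, c("country", "period", "education"))
  etfr <- 5 * rowsum(w$truth$value, key)
  parts <- do.call(rbind, strsplit(rownames(etfr), "\r", fixed = TRUE))
  by_pe <- tapply(etfr[, 1], list(parts[, 2], parts[, 3]), mean)
  expect_true(all(by_pe[, "No Education"] >= by_pe[, "Higher Education"]))
})
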