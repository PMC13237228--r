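test_that("cleaning applies the three filters with their scopes", {
  base <- tiny_world()$surveys
  extra <- base[rep(1, 3), ]
  extra$education <- c("Higher Education", "No Education",
                       "Primary Education")
  extra$births <- c(31, 31, 5)
  extra$value <- c(0.05, 0.05, 1.7)
  raw <- rbind(base, extra)
  cleaned <- clean_observations(raw)
  removed <- attr(cleaned, "removed")

  # birth-count rule is specific to higher education
  expect_true(any(removed$rule == "higher_ed_birth_count" &
                    removed$births == 31))
  expect_false(any(removed$education == "No Education" &
                     removed$births == 31, na.rm = TRUE))
  expect_true(any(cleaned$education == "No Education" &
                    cleaned$births == 31))
  # hard rate ceiling
  expect_true(any(removed$rule == "rate_ceiling" & removed$value == 1.7))
  expect_true(all(cleaned$value <= 1))
})

test_that("cleaning is idempotent", {
  once <- clean_observations(tiny_world()$surveys)
  twice <- clean_observations(once)
  attr(once, "removed") <- attr(twice, "removed") <- NULL
  expect_identical(twice, once)
})

test_that("robust-outlier rule removes gross deviations from the cell median", {
  w <- tiny_world()
  raw <- w$surveys
  i <- which(raw$education == "No Education" & raw$age_group == "25-29")[1]
  spike <- raw[i, ]
  spike$value <- raw$value[i] * 0 + 0.95   # below ceiling, far above median
  raw <- rbind(raw, spike)
  cleaned <- clean_observations(raw)
  expect_true(any(attr(cleaned, "removed")$rule == "robust_outlier"))
})

test_that("noise-free rates are reproduced exactly by the refit", {
  cfg <- world_config(
    region_assignment = c(CountryA = "sub-Saharan Africa"),
    periods = "2000-2005", decline_rate = 0)
  truth <- generate_true_schedules(cfg)
  spec <- world_lattice(cfg)
  obs <- truth[c("country", "period", "age_group", "education", "value")]
  init <- fit_glm_init(obs, spec, family = "gaussian")
  rel <- abs(init$predicted$value[match(edufert:::cell_key(truth),
                                        edufert:::cell_key(init$predicted))] -
               truth$value) / truth$value
  expect_lt(max(rel), 1e-6)
})

test_that("the completed lattice extrapolates to unobserved periods", {
  w <- tiny_world()
  spec <- world_lattice(w$config)
  late <- w$surveys[edufert:::period_start(w$surveys$period) >= 2000, ]
  init <- fit_glm_init(clean_observations(late), spec)
  early <- init$predicted[init$predicted$period == "1990-1995", ]
  expect_identical(nrow(early), 3L * 7L * 4L)
  expect_true(all(is.finite(early$value) & early$value > 0))
  expect_true(all(init$se$value[is.finite(init$se$value)] >= 0))
})

test_that("region assignment changes predictions when regions differ", {
  w <- tiny_world()
  obs <- clean_observations(w$surveys)
  specA <- world_lattice(w$config)
  regB <- w$config$region_assignment
  regB["CountryB"] <- "Latin America"   # move a country across regions
  specB <- lattice_spec(specA$countries, specA$periods,
                        region_assignment = regB)
  pA <- fit_glm_init(obs, specA)$predicted
  pB <- fit_glm_init(obs, specB)$predicted
  expect_gt(max(abs(pA$value - pB$value)), 1e-8)
})

test_that("predictions are invariant to observation row order", {
  w <- tiny_world()
  obs <- clean_observations(w$surveys)
  perm <- withr::with_seed(7, sample(nrow(obs)))
  p1 <- fit_glm_init(obs, world_lattice(w$config))$predicted
  p2 <- fit_glm_init(obs[perm, ], world_lattice(w$config))$predicted
  expect_equal(p1$value, p2$value, tolerance = 1e-8)
})

test_that("prior statistics implement their grouped definitions", {
  spec <- lattice_spec(
    countries = c("CountryA", "CountryB"),
    periods = c("2000-2005", "2005-2010"),
    region_assignment = c(CountryA = "Europe", CountryB = "Europe"))
  grid <- lattice_cells(spec)
  pred <- grid; pred$value <- 0.2

  # constant SEs: zero spread, mean preserved
  se <- grid; se$value <- 0.03
  st <- derive_prior_statistics(as_glm_init(pred, se, spec))
  expect_equal(unname(st$sigma_e), rep(0, 4))
  expect_equal(unname(st$mu_e), rep(0.03, 4))

  # two-point SE distribution within one education level
  se2 <- se
  in_grp <- se2$education == "No Education"
  se2$value[in_grp] <- rep(c(0.01, 0.03), length.out = sum(in_grp))
  st2 <- derive_prior_statistics(as_glm_init(pred, se2, spec))
  expect_equal(unname(st2$sigma_e["No Education"]),
               stats::sd(rep(c(0.01, 0.03), length.out = sum(in_grp))),
               tolerance = 1e-12)
  expect_identical(dim(st2$sigma_ae), c(7L, 4L))

  # top-education derived totals drive sigma_etfr_e4
  pred3 <- pred
  top <- pred3$education == "Higher Education"
  pred3$value[top] <- rep(c(0.1, 0.2), each = 7,
                          length.out = sum(top))
  st3 <- derive_prior_statistics(as_glm_init(pred3, se, spec))
  etfr_top <- 5 * tapply(pred3$value[top],
                         paste(pred3$country[top], pred3$period[top]), sum)
  expect_equal(st3$sigma_etfr_e4, stats::sd(etfr_top), tolerance = 1e-12)
})

test_that("poisson and gaussian paths broadly agree on dense data", {
  w <- tiny_world()
  obs <- clean_observations(w$surveys)
  spec <- world_lattice(w$config)
  pp <- fit_glm_init(obs, spec, family = "poisson")$predicted
  pg <- fit_glm_init(obs, spec, family = "gaussian")$predicted
  expect_gt(stats::cor(pp$value, pg$value), 0.95)
})
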