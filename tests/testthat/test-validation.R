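test_that("holdout plans remove exactly the requested rows", {
  bench <- data.frame(country = rep(paste0("C", 1:10), each = 100),
                      period = "2000-2005", age_group = "25-29",
                      value = 0.2)
  h <- make_holdout(bench, "random_fraction", fraction = 0.05, seed = 1)
  expect_identical(nrow(h$plan$held_out), 50L)
  expect_identical(nrow(h$benchmark), 950L)
  h2 <- make_holdout(bench, "random_fraction", fraction = 0.05, seed = 1)
  expect_identical(h$plan$held_out, h2$plan$held_out)

  hc <- make_holdout(bench, "countries", countries = "C3", seed = 1)
  expect_identical(nrow(hc$plan$held_out), 100L)
  expect_false("C3" %in% hc$benchmark$country)

  expect_error(make_holdout(bench, "random_fraction", fraction = 1.2),
               "fraction")
  expect_error(make_holdout(bench, "countries", countries = "Xanadu"),
               "Xanadu")
  expect_equal(default_holdout_fractions(),
               c(0.05, 0.10, 0.15, 0.20, 0.30))
})

test_that("coverage counts held-out values inside central intervals", {
  cells <- data.frame(country = paste0("C", 1:3), period = "2000-2005",
                      age_group = "25-29")
  draws <- cbind(1:100, 1:100, 1:100)
  fd <- fake_draws(draws, cells)
  # 80% interval of 1..100 is [10.9, 90.1]: put two values in, one out
  held <- cells
  held$value <- c(50, 89, 99)
  cov80 <- coverage(fd, held, levels = 0.80)
  expect_equal(cov80$fraction, 2 / 3)
  expect_identical(cov80$covered, 2L)

  # degenerate draws covering the value at every level
  fd1 <- fake_draws(matrix(0.2, 100, 3), cells)
  held1 <- cells; held1$value <- 0.2
  expect_equal(coverage(fd1, held1)$fraction, rep(1, 3))
  # values above every draw are never covered
  held2 <- cells; held2$value <- 101
  expect_equal(coverage(fd, held2)$fraction, rep(0, 3))
})

test_that("coverage is monotone in the interval level", {
  fit <- tiny_fit()
  w <- tiny_world()
  h <- make_holdout(w$benchmark, "random_fraction", fraction = 0.2,
                    seed = 3)
  covr <- coverage(fit, h$plan$held_out, levels = c(0.5, 0.8, 0.9))
  expect_true(all(diff(covr$fraction) >= 0))
  bc <- attr(covr, "by_country")
  expect_true(all(c("country", "level", "fraction") %in% names(bc)))
})

test_that("missing held-out cells are reported by key", {
  cells <- data.frame(country = "C1", period = "2000-2005",
                      age_group = "25-29")
  fd <- fake_draws(matrix(1:10, ncol = 1), cells)
  held <- data.frame(country = "C9", period = "2000-2005",
                     age_group = "25-29", value = 1)
  expect_error(coverage(fd, held), "C9")
})

test_that("the validation suite emits one deterministic row per plan-level", {
  inputs <- tiny_inputs()
  w <- tiny_world()
  plans <- list(
    make_holdout(w$benchmark, "random_fraction", fraction = 0.1, seed = 4),
    make_holdout(w$benchmark, "random_fraction", fraction = 0.1, seed = 4),
    make_holdout(w$benchmark, "countries", countries = "CountryC",
                 seed = 4))
  tab <- run_validation_suite(inputs, plans, chains = 2, warmup = 150,
                              iterations = 200, seed = 9)
  expect_identical(nrow(tab), 9L)
  expect_setequal(unique(tab$level), c(0.5, 0.8, 0.9))
  # identical plans with the same seeds give identical rows
  expect_identical(tab[tab$plan == tab$plan[1], ][1:3, ],
                   tab[tab$plan == tab$plan[1], ][4:6, ],
                   ignore_attr = TRUE)
  # held-out rows never enter the refit as observed nodes
  red <- model_inputs(inputs$init, plans[[3]]$benchmark, inputs$weights,
                      inputs$prior_stats, prev_etfr = inputs$prev_etfr)
  expect_identical(build_model(red)$n_benchmark_obs,
                   nrow(w$benchmark) - nrow(plans[[3]]$plan$held_out))
})

test_that("alternative-benchmark comparison includes the 95% level", {
  fit <- tiny_fit()
  alt <- tiny_world()$benchmark
  agree <- compare_alt_benchmark(fit, alt)
  expect_setequal(agree$level, c(0.5, 0.8, 0.9, 0.95))
  expect_true(all(diff(agree$fraction) >= 0))
  far <- alt; far$value <- alt$value + 10
  expect_equal(compare_alt_benchmark(fit, far)$fraction, rep(0, 4))
})

test_that("model-generated worlds are reproducible and coherent", {
  inputs <- tiny_inputs()
  s1 <- simulate_from_model(inputs, seed = 21)
  s2 <- simulate_from_model(inputs, seed = 21)
  expect_identical(s1, s2)
  expect_true(all(s1$eafr_true$value > 0))
  # the noise-free benchmark is the exact weighted aggregation
  k <- edufert:::cell_key(s1$eafr_true,
                          c("country", "period", "age_group"))
  wv <- inputs$weights$value[match(edufert:::cell_key(s1$eafr_true),
                                   edufert:::cell_key(inputs$weights))]
  agg <- rowsum(s1$eafr_true$value * wv, k)
  expect_equal(s1$benchmark$value,
               agg[match(unique(k), rownames(agg)), 1],
               ignore_attr = TRUE, tolerance = 1e-12)
})
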