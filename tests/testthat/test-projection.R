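test_that("annual changes difference the series in transform space", {
  expect_equal(unname(annual_changes(rep(7, 5), 2000:2004, "log")),
               rep(0, 4))
  # doubling each year in log space
  x <- 3 * 2^(0:5)
  expect_equal(unname(annual_changes(x, 2000:2005, "log")),
               rep(log(2), 5))
  expect_equal(unname(annual_changes(c(100, 90, 81), 2000:2002, "log")),
               c(log(90 / 100), log(81 / 90)))
  # interior gaps are interpolated linearly in transform space
  r <- annual_changes(c(100, 81), c(2000, 2002), "log")
  expect_equal(unname(r), rep(log(0.9), 2))
  expect_error(annual_changes(c(1, 2), c(2000, 2010), "log"),
               "consecutive missing")
})

test_that("recency weights are normalised power weights", {
  expect_equal(unname(recency_weights(2000:2004, 0)), rep(0.2, 5))
  expect_equal(unname(recency_weights(2001:2003, 1)), c(1, 2, 3) / 6)
  for (om in c(0, 0.5, 1, 2.75)) {
    expect_equal(sum(recency_weights(1991:2016, om)), 1)
  }
  expect_error(recency_weights(2000:2004, -1), "non-negative")
})

test_that("weighted mean AROC reduces correctly at the edges", {
  r <- c(0.1, -0.2, 0.05, 0)
  expect_equal(weighted_aroc(r, rep(0.25, 4)), mean(r))
  expect_equal(weighted_aroc(r, c(0, 0, 1, 0)), 0.05)
  expect_equal(weighted_aroc(rep(-0.03, 4), recency_weights(1:4, 2)), -0.03)
  expect_error(weighted_aroc(r, c(0.5, 0.5)), "equal length")
})

test_that("omega selection prefers recency under acceleration, smallest on ties", {
  # constant-rate series: every omega reproduces the rate, smallest wins
  x <- decay_series(100, -0.04, n = 15)
  expect_equal(select_omega(x, 2000:2014, "log"), 0)

  # accelerating decline: recent changes are steeper, recency weighting
  # backcasts better
  t <- 0:19
  x <- 100 * exp(-0.01 * t - 0.002 * t^2)
  expect_gt(select_omega(x, 2000:2019, "log"), 0)

  expect_warning(om <- select_omega(c(5, 4, 3, 2), 2000:2003, "linear",
                                    holdout_years = 3),
                 "too short")
  expect_equal(om, 1)
})

test_that("the AROC fit projects constant-rate series exactly", {
  fit <- aroc_fit(c(100, 90, 81), 2000:2002, transform = "log", omega = 1)
  expect_equal(unname(coef(fit)["rate"]), log(0.9))
  expect_equal(unname(predict(fit, years = 2004)), 65.61,
               tolerance = 1e-9)

  # constant series project flat
  fit <- aroc_fit(rep(12, 6), 2000:2005, transform = "log", omega = 0)
  expect_equal(unname(predict(fit, horizon_year = 2010)), rep(12, 5))

  # logit-transform projections stay inside (0, 1)
  p <- plogis(seq(-2, 2.5, length.out = 10))
  fit <- aroc_fit(p, 2000:2009, transform = "logit", omega = 2)
  pr <- predict(fit, horizon_year = 2050)
  expect_true(all(pr > 0 & pr < 1))

  # log-transform projections stay positive even for steep declines
  fit <- aroc_fit(decay_series(5, -0.5, n = 10), 2000:2009,
                  transform = "log", omega = 0)
  expect_true(all(predict(fit, horizon_year = 2040) > 0))
})

test_that("fit methods are mutually consistent", {
  set.seed(11)
  x <- decay_series(80, -0.05, n = 20) * exp(rnorm(20, 0, 0.03))
  fit <- aroc_fit(x, 1997:2016, transform = "log")

  expect_named(coef(fit), c("rate", "omega"))
  expect_equal(unname(residuals(fit)), unname(fit$changes - fit$rate))
  expect_equal(length(fitted(fit)), 20L)
  expect_equal(unname(fitted(fit)[1]), x[1])

  # simulate: seeded draws are reproducible and respect the log domain
  s1 <- simulate(fit, nsim = 3, seed = 5)
  s2 <- simulate(fit, nsim = 3, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0))
  expect_equal(nrow(s1), 20L)

  out <- capture.output({print(fit); print(summary(fit))})
  expect_true(any(grepl("omega", out)))

  # noiseless simulation reproduces the deterministic path
  s0 <- simulate(fit, nsim = 1, sigma = 0)
  expect_equal(s0$sim_1,
               unname(exp(log(x[1]) + (0:19) * fit$rate)))
})

test_that("weighted AROC agrees with a brute-force oracle on random series", {
  set.seed(97)
  for (k in 1:200) {
    n <- sample(3:40, 1)
    years <- 1990 + seq_len(n) - 1
    x <- exp(cumsum(rnorm(n, -0.02, 0.1)) + 4)
    om <- sample(c(0, 0.25, 1, 2, 3), 1)
    fit <- aroc_fit(x, years, transform = "log", omega = om)

    # oracle: explicit loop over consecutive log-ratios and power weights
    r <- numeric(n - 1)
    w <- numeric(n - 1)
    for (i in 2:n) {
      r[i - 1] <- log(x[i]) - log(x[i - 1])
      w[i - 1] <- (years[i] - years[2] + 1)^om
    }
    w <- w / sum(w)
    expect_equal(unname(fit$rate), sum(r * w), tolerance = 1e-12)
  }
})

test_that("the rate estimate is unbiased under a constant noisy trend", {
  set.seed(19)
  r_true <- -0.04
  sigma <- 0.05
  n <- 20
  for (om in c(0, 1, 3)) {
    est <- replicate(300, {
      x <- 50 * exp(r_true * (0:(n - 1)) + rnorm(n, 0, sigma))
      aroc_fit(x, 2000 + 0:(n - 1), transform = "log", omega = om)$rate
    })
    expect_lt(abs(mean(est) - r_true), 3 * sd(est) / sqrt(length(est)))
    expect_lt(median(abs(est - r_true)), 3 * sigma / sqrt(n))
  }
})

test_that("panel projection emits one path per series", {
  panel <- generate_panel(scenario_spec(seed = 3, n_provinces = 4,
                                        sigma_scale = 0),
                          sdg_registry())
  proj <- project_panel(panel, horizon = 2030L)
  paths <- unique(proj[, c("location_id", "indicator_id", "sex")])
  expect_equal(nrow(paths), 5L * 28L * 3L)
  expect_true(all(proj$year %in% 2017:2030))
  expect_true(all(proj$omega %in% seq(0, 3, by = 0.25)))
})
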