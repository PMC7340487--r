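test_that("the generator is deterministic and respects its spec", {
  spec <- scenario_spec(seed = 42, n_provinces = 5)
  p1 <- generate_panel(spec)
  p2 <- generate_panel(spec)
  expect_identical(p1, p2)
  expect_error(scenario_spec(n_provinces = 5), "seed")

  # cardinality: provinces + national, 28 indicators, 3 sexes, 27 years
  expect_equal(nrow(p1), 6L * 28L * 3L * 27L)
  expect_setequal(unique(p1$region),
                  c("eastern", "central", "western", "national"))
})

test_that("noise-free series are exactly trend-following and recoverable", {
  spec <- scenario_spec(seed = 8, n_provinces = 3, sigma_scale = 0)
  panel <- generate_panel(spec)
  params <- default_indicator_params()

  # pick a log indicator and check the generator's closed form
  s <- panel[panel$location_id == "P01" & panel$indicator_id == "3.2.2" &
               panel$sex == "both", ]
  r_design <- params$rate[params$indicator_id == "3.2.2"]
  expect_equal(unname(diff(log(s$value))), rep(r_design, 26),
               tolerance = 1e-12)

  # the AROC fit recovers the design rate to machine precision
  fit <- aroc_fit(s$value, s$year, transform = "log")
  expect_equal(unname(fit$rate), r_design, tolerance = 1e-12)
  expect_equal(fit$omega, 0)  # all omegas tie, smallest returned
})

test_that("designed sex effects appear as constant male/female ratios", {
  params <- default_indicator_params()
  params$sex_effect[params$indicator_id == "3.3.2"] <- log(1.8)
  spec <- scenario_spec(seed = 13, n_provinces = 3, params = params,
                        sigma_scale = 0)
  panel <- generate_panel(spec)
  tb <- panel[panel$indicator_id == "3.3.2" & panel$location_id == "P02", ]
  ratio <- tb$value[tb$sex == "male"] / tb$value[tb$sex == "female"]
  expect_equal(ratio, rep(1.8, 27), tolerance = 1e-12)
})

test_that("noisy sex ratios converge to the design at root-n rate", {
  params <- default_indicator_params()
  params$sex_effect[params$indicator_id == "3.3.2"] <- log(1.8)
  spec <- scenario_spec(seed = 29, n_provinces = 20, params = params)
  panel <- generate_panel(spec)
  tb <- panel[panel$indicator_id == "3.3.2" & panel$region != "national", ]
  lr <- log(tb$value[tb$sex == "male"]) - log(tb$value[tb$sex == "female"])
  n <- length(lr)
  sigma <- params$sigma[params$indicator_id == "3.3.2"] * sqrt(2)
  expect_lt(abs(mean(lr) - log(1.8)), 4 * sigma / sqrt(n))
})

test_that("published fixture values are retrievable", {
  expect_equal(fixture_value("2.2.1", "male", 2013), 8.7)
  expect_equal(fixture_value("u5mr", "rural", 2016), 12.4)

  s <- fixture_national_scores()
  expect_equal(s$score[s$topic == "infectious"], c(40, 63, 100, 49, 80))

  ti <- fixture_topic_indices()
  expect_equal(ti$index_2016[ti$topic == "road_injury"], 63.6)
  # endpoint-consistency flags: road injury, UHC and environmental
  # exposure reproduce their printed rates from printed endpoints
  expect_true(all(ti$endpoint_consistent[
    ti$topic %in% c("road_injury", "uhc", "env_exposure")]))
})

test_that("achievement scenarios hit their designed counts end-to-end", {
  reg <- sdg_registry()
  for (target in c(0L, 5L, 28L)) {
    panel <- make_achievement_scenario(target, seed = 100 + target,
                                       registry = reg, n_provinces = 3)
    res <- suppressWarnings(sdg_pipeline(panel, reg))
    nat <- res$progress$achievement[
      res$progress$achievement$region == "national", ]
    expect_equal(nat$n_achieved, target)
    expect_equal(nat$n_total, 28L)
  }
  expect_error(make_achievement_scenario(40, seed = 1), "n_achieved")
})
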