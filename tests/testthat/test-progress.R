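test_that("achievement counting is inclusive at the threshold", {
  expect_equal(count_achieved(rep(100, 28)), 28L)
  expect_equal(count_achieved(rep(89.9, 28)), 0L)
  expect_equal(count_achieved(c(100, 89.9, 90)), 2L)
  expect_warning(n <- count_achieved(c(95, NA, 80)), "missing score")
  expect_equal(n, 1L)

  # monotone non-increasing in the threshold
  set.seed(5)
  s <- runif(28, 0, 100)
  counts <- vapply(c(50, 70, 90, 95), function(th) count_achieved(s, th),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("annual change rates reproduce the published worked examples", {
  expect_equal(annual_change_rate(63.6, 70.0, 2016, 2020), 1.6)
  expect_equal(round(annual_change_rate(54.4, 69.2, 2016, 2030), 1), 1.1)
  expect_equal(annual_change_rate(50, 50, 2016, 2030), 0)
  # antisymmetric under endpoint exchange
  expect_equal(annual_change_rate(80, 60, 2016, 2026),
               -annual_change_rate(60, 80, 2016, 2026))
  expect_error(annual_change_rate(1, 2, 2020, 2020), "after")
})

test_that("disparity ratios match the published stratified values", {
  expect_equal(round(disparity_ratio(12.4, 5.2), 1), 2.4)   # rural/urban U5MR
  expect_equal(round(disparity_ratio(8.7, 7.4), 1), 1.2)    # male/female stunting
  expect_equal(disparity_ratio(3.3, 3.3), 1.0)
  # reciprocity to floating tolerance
  expect_equal(disparity_ratio(8.7, 7.4), 1 / disparity_ratio(7.4, 8.7))
  expect_error(disparity_ratio(1, 0), "positive")
})

test_that("regional summaries average provinces and exclude SARs", {
  ti <- data.frame(
    location_id = c("P01", "P02", "P03", "P04", "HK", "CN"),
    region = c("eastern", "eastern", "western", "central", "SAR",
               "national"),
    sex = "both",
    topic = "uhc", year = 2016L,
    index = c(80, 70, 50, 60, 95, 66),
    stringsAsFactors = FALSE)
  rs <- regional_summary(ti)
  expect_setequal(rs$region, c("eastern", "central", "western"))
  expect_equal(rs$mean[rs$region == "eastern"], 75)
  expect_equal(rs$mean[rs$region == "western"], 50)   # single province
  expect_equal(rs$n_provinces[rs$region == "central"], 1L)

  # all provinces equal -> all regional means equal
  ti$index[1:4] <- 55
  rs <- regional_summary(ti)
  expect_true(all(rs$mean == 55))

  ti$region[1] <- NA
  expect_error(regional_summary(ti), "unmapped")
})

test_that("a generated eastern advantage shows up in the regional means", {
  panel <- generate_panel(scenario_spec(seed = 21, n_provinces = 8,
                                        sigma_scale = 0))
  scores <- suppressWarnings(scale_panel(panel))
  topics <- suppressWarnings(aggregate_topics(scores))
  rs <- regional_summary(topics[topics$sex == "both" &
                                  topics$year == 2016, ])
  # region effects favour the east on most topics
  cmp <- merge(rs[rs$region == "eastern", c("topic", "mean")],
               rs[rs$region == "western", c("topic", "mean")],
               by = "topic", suffixes = c("_e", "_w"))
  expect_gt(mean(cmp$mean_e > cmp$mean_w), 0.5)
})
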