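test_that("Tukey fences flag exactly the points beyond 1.5 IQR", {
  expect_equal(tukey_outliers(c(5, 5, 5, 5, 5)), rep(FALSE, 5))

  # type-7 quartiles of (1,2,3,4,100): Q1 = 2, Q3 = 4, fences (-1, 7)
  expect_equal(tukey_outliers(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))

  expect_error(tukey_outliers(c(1, 2, 3)), "at least 4")

  # independent brute-force check of the fence rule on random draws
  set.seed(41)
  for (k in 1:25) {
    x <- c(rnorm(12), sample(c(-50, 50), 2))
    q <- unname(quantile(x, c(0.25, 0.75), type = 7))
    manual <- x < q[1] - 1.5 * (q[2] - q[1]) | x > q[2] + 1.5 * (q[2] - q[1])
    expect_identical(tukey_outliers(x), manual)
  }
})

test_that("anchors take the trimmed worst value and the resolved target", {
  def <- fake_definition(target_value = 2)
  a <- resolve_anchors(c(10, 8, 12, 9), 1990:1993, def)
  expect_equal(a$worst, 12)
  expect_equal(a$target, 2)

  # an extreme value is trimmed before the worst is taken
  a <- resolve_anchors(c(10, 8, 12, 9, 300), 1990:1994, def)
  expect_equal(a$worst, 12)

  # no-increase targets resolve to the baseline-year value
  def_ni <- fake_definition(transform = "logit", target_type = "no_increase",
                            target_value = NA, baseline_year = 2015L)
  vals <- c(0.06, 0.09, 0.075, 0.08, 0.084)
  a <- resolve_anchors(vals, 2011:2015, def_ni)
  expect_equal(a$target, 0.084)
  expect_equal(a$worst, 0.09)

  # elimination targets resolve to half the smallest positive value
  def_el <- fake_definition(transform = "logit", target_type = "elimination",
                            target_value = NA)
  a <- resolve_anchors(c(0.4, 0.3, 0.25, 0.2), 2010:2013, def_el)
  expect_equal(a$target, 0.1)

  # anchoring ignores the order of the years
  a1 <- resolve_anchors(c(10, 8, 12, 9), 1990:1993, def)
  a2 <- resolve_anchors(c(9, 12, 8, 10), c(1993, 1992, 1991, 1990), def)
  expect_equal(a1$worst, a2$worst)

  expect_error(resolve_anchors(c(2, 2, 2, 2), 1990:1993, def), "degenerate")
  expect_error(resolve_anchors(c(10, 9), 1990:1991, def), "insufficient")
})

test_that("scaling maps anchors to 0/100 with log-space interpolation", {
  def <- fake_definition(target_value = 1)
  a <- resolve_anchors(c(100, 95, 90, 85), 1990:1993, def)
  expect_equal(a$worst, 100)
  expect_equal(scale_value(1, a), 100)    # at target
  expect_equal(scale_value(100, a), 0)    # at worst
  expect_equal(scale_value(10, a), 50)    # geometric midpoint
  expect_equal(scale_value(150, a), 0)    # beyond worst clips
  expect_equal(scale_value(0.5, a), 100)  # beyond target clips
  expect_error(scale_value(NaN, a), "non-finite")

  # with a linear transform and anchors (0, 100) the score equals the value
  def_lin <- fake_definition(direction = "higher_better",
                             transform = "linear", target_value = 100)
  a_lin <- resolve_anchors(c(0, 20, 35, 41), 1990:1993, def_lin)
  for (x in c(0, 12.5, 50, 99)) expect_equal(scale_value(x, a_lin), x)
})

test_that("scores are clipped to [0,100] and monotone toward the target", {
  set.seed(73)
  def <- fake_definition(target_value = 1)
  for (k in 1:50) {
    vals <- exp(rnorm(8, mean = 3, sd = 1)) + 1.5
    a <- resolve_anchors(vals, 1990:1997, def)
    x <- sort(exp(runif(20, -1, 6)))
    s <- scale_value(x, a)
    expect_true(all(s >= 0 & s <= 100))
    # lower is better: decreasing x must not decrease the score
    expect_true(all(diff(rev(s)) >= 0))
  }
})

test_that("panel scaling reproduces hand-computed scores and records anchors", {
  # a series that reaches its target scores exactly 100 there
  def_years <- 1990:1996
  at_target <- series_panel(c(60, 50, 45, 40, 35, 30, 25), def_years)
  scores <- scale_panel(at_target)
  expect_equal(scores$score[scores$year == 1996], 100)

  # spreadsheet-style recomputation for every record
  vals <- c(54, 48, 44, 41, 36, 33, 30)
  panel <- series_panel(vals, def_years)
  scores <- scale_panel(panel)
  worst <- max(vals)
  target <- 25
  manual <- pmin(100, pmax(0, 100 * (log(vals) - log(worst)) /
                             (log(target) - log(worst))))
  expect_equal(scores$score, manual)
  expect_equal(unique(scores$worst), worst)
  expect_equal(unique(scores$target), target)
})

test_that("histories that always met an absolute target grade pass/fail", {
  # childhood-wasting-like series: every value below the 5% ceiling
  def <- fake_definition(transform = "logit", target_value = 0.05)
  a <- resolve_anchors(c(0.030, 0.028, 0.025, 0.022), 1990:1993, def)
  expect_true(a$inverted)
  expect_equal(scale_value(0.02, a), 100)
  expect_equal(scale_value(0.05, a), 100)  # at target still counts
  expect_equal(scale_value(0.06, a), 0)    # deterioration past the target
})

test_that("failing series are dropped softly while the rest are scored", {
  good <- series_panel(c(54, 48, 44, 41), 1990:1993)
  degenerate <- series_panel(rep(25, 4), 1990:1993, location_id = "P02")
  expect_warning(scores <- scale_panel(rbind(good, degenerate)),
                 "could not be scored")
  expect_setequal(unique(scores$location_id), "P01")
  expect_equal(nrow(scores), 4L)
})
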