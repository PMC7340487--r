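#' Default per-indicator generator parameters
#'
#' Baseline levels (national, both sexes, 1990), annual transform-space
#' drifts, curvature, sex and region effects and observation noise used by
#' [generate_panel()]. The values are chosen to be epidemiologically
#' plausible for a middle-income country over 1990-2016: mortality and
#' incidence rates decline log-linearly at a few percent per year, coverage
#' indicators rise in logit space, childhood overweight and alcohol exposure
#' worsen. Sex effects are transform-space male-minus-female gaps (e.g.
#' `log(1.8)` for tuberculosis incidence gives a male/female ratio of 1.8 at
#' every year).
#'
#' @return A data frame with columns `indicator_id`, `baseline`, `rate`,
#'   `accel`, `sex_effect`, `region_delta`, `sigma`.
#' @export
default_indicator_params <- function() {
  p <- function(id, baseline, rate, sex_effect = 0.1, region_delta = 0.2,
                sigma = 0.02, accel = 0) {
    data.frame(indicator_id = id, baseline = baseline, rate = rate,
               accel = accel, sex_effect = sex_effect,
               region_delta = region_delta, sigma = sigma,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    p("2.2.1",  0.320, -0.055, sex_effect = log(1.2)),
    p("2.2.2a", 0.035, -0.020, sex_effect = 0.05),
    p("2.2.2b", 0.040, +0.035, sex_effect = log(1.3)),
    p("3.1.1",  88,    -0.055, sex_effect = 0),
    p("3.1.2",  0.60,  +0.150, sex_effect = 0, sigma = 0.05),
    p("3.2.1",  54,    -0.065, sex_effect = log(1.15)),
    p("3.2.2",  30,    -0.070, sex_effect = log(1.15)),
    p("3.b.1",  0.85,  +0.060, sex_effect = 0, sigma = 0.05),
    p("3.7.1",  0.75,  +0.030, sex_effect = 0, sigma = 0.05),
    p("3.3.1",  0.020, +0.040, sex_effect = log(3.5), sigma = 0.05),
    p("3.3.2",  170,   -0.035, sex_effect = log(1.8)),
    p("3.3.3",  0.60,  -0.180, sex_effect = log(1.3), sigma = 0.08),
    p("3.3.4",  90,    -0.020, sex_effect = log(1.7)),
    p("3.3.5",  5.0,   -0.060, sex_effect = 0.1),
    p("3.4.1",  450,   -0.018, sex_effect = log(1.5), sigma = 0.01),
    p("3.4.2",  14,    -0.050, sex_effect = log(1.4)),
    p("3.5.2",  0.060, +0.030, sex_effect = log(5.9), sigma = 0.03),
    p("3.a.1",  0.300, -0.010, sex_effect = 3.5, sigma = 0.02),
    p("3.6.1",  20,    -0.010, sex_effect = log(2.8)),
    p("3.9.1",  120,   -0.025, sex_effect = log(1.3)),
    p("3.9.2",  8,     -0.120, sex_effect = 0.1, sigma = 0.05),
    p("3.9.3",  4,     -0.050, sex_effect = log(1.5)),
    p("11.6.2", 55,    +0.200, sex_effect = 0, sigma = 1.5),
    p("7.1.2",  0.50,  -0.070, sex_effect = 0, sigma = 0.03),
    p("6.1.1",  0.30,  -0.060, sex_effect = 0, sigma = 0.03),
    p("6.2.1a", 0.50,  -0.060, sex_effect = 0, sigma = 0.03),
    p("6.2.1b", 0.35,  -0.040, sex_effect = 0, sigma = 0.03),
    p("3.8.1",  45,    +0.900, sex_effect = 0, region_delta = 5, sigma = 0.8)
  ))
}

#' Specify a synthetic panel scenario
#'
#' Describes a province-by-indicator-by-sex-by-year panel with log-linear
#' (transform-space) trends, province, region and sex effects and Gaussian
#' observation noise in transform space. The seed fully determines the
#' generated panel and must be given explicitly.
#'
#' @param seed integer seed (required; no hidden default).
#' @param n_provinces number of provinces, default 31 (11 eastern, 8
#'   central, 12 western, mirroring the official grouping of mainland
#'   China).
#' @param years observation years, default `1990:2016`.
#' @param params per-indicator parameter table, default
#'   [default_indicator_params()].
#' @param province_sd standard deviation of transform-space province
#'   intercepts.
#' @param sigma_scale multiplier on every indicator's noise sd (0 gives
#'   exactly trend-following series).
#' @param include_national add a national location whose transform-space
#'   values are the province means (default `TRUE`).
#' @return A list of class `"sdg_scenario"`.
#' @export
scenario_spec <- function(seed, n_provinces = 31L, years = 1990:2016,
                          params = default_indicator_params(),
                          province_sd = 0.10, sigma_scale = 1,
                          include_national = TRUE) {
  if (missing(seed)) stop("scenario_spec requires an explicit seed",
                          call. = FALSE)
  stopifnot(n_provinces >= 3, sigma_scale >= 0, province_sd >= 0)
  structure(list(seed = as.integer(seed), n_provinces = as.integer(n_provinces),
                 years = as.integer(years), params = params,
                 province_sd = province_sd, sigma_scale = sigma_scale,
                 include_national = include_national),
            class = "sdg_scenario")
}

# region assignment: first ~35% eastern, next ~26% central, rest western
scenario_regions <- function(n_provinces) {
  n_e <- max(1L, round(n_provinces * 11 / 31))
  n_c <- max(1L, round(n_provinces * 8 / 31))
  n_w <- n_provinces - n_e - n_c
  rep(c("eastern", "central", "western"), times = c(n_e, n_c, n_w))
}

#' Generate a synthetic indicator panel
#'
#' For province p, indicator i, sex s and year t the transform-space value
#' is `f(baseline) + rate * (t - 1990) + accel * (t - 1990)^2 +
#' province_effect + region_effect + sex_effect / 2 * (+1 male / -1 female)
#' + noise`. Region effects are signed so that western provinces are worse
#' off on every indicator regardless of its direction. The both-sex series
#' is the transform-space mean of the two sex series; the national series
#' the transform-space mean over provinces.
#'
#' @param spec an `"sdg_scenario"` from [scenario_spec()].
#' @param registry registry data frame.
#' @return A validated panel data frame.
#' @export
#' @examples
#' panel <- generate_panel(scenario_spec(seed = 1, n_provinces = 4,
#'                                       sigma_scale = 0))
generate_panel <- function(spec, registry = sdg_registry()) {
  stopifnot(inherits(spec, "sdg_scenario"))
  set.seed(spec$seed)
  years <- spec$years
  t <- years - min(years)
  regions <- scenario_regions(spec$n_provinces)
  prov_ids <- sprintf("P%02d", seq_len(spec$n_provinces))
  region_score <- c(eastern = -1, central = 0, western = 1)

  out <- vector("list", nrow(spec$params))
  for (k in seq_len(nrow(spec$params))) {
    par <- spec$params[k, ]
    def <- registry_row(registry, par$indicator_id)
    f0 <- apply_transform(par$baseline, def$transform)
    bad_sign <- if (def$direction == "lower_better") 1 else -1
    trend <- f0 + par$rate * t + par$accel * t^2
    prov_eff <- stats::rnorm(spec$n_provinces, 0, spec$province_sd)
    if (def$transform == "linear") {
      prov_eff <- prov_eff * abs(par$baseline) * 0.2
    }

    rows <- vector("list", spec$n_provinces)
    f_mat_m <- matrix(NA_real_, spec$n_provinces, length(years))
    f_mat_f <- matrix(NA_real_, spec$n_provinces, length(years))
    for (p in seq_len(spec$n_provinces)) {
      reg_eff <- bad_sign * region_score[[regions[p]]] * par$region_delta *
        (if (def$transform == "linear") abs(par$baseline) * 0.1 else 1)
      base_p <- trend + prov_eff[p] + reg_eff
      noise_m <- stats::rnorm(length(years), 0,
                              par$sigma * spec$sigma_scale)
      noise_f <- stats::rnorm(length(years), 0,
                              par$sigma * spec$sigma_scale)
      f_m <- base_p + par$sex_effect / 2 + noise_m
      f_f <- base_p - par$sex_effect / 2 + noise_f
      f_mat_m[p, ] <- f_m
      f_mat_f[p, ] <- f_f
      rows[[p]] <- data.frame(
        location_id = prov_ids[p], region = regions[p],
        indicator_id = par$indicator_id,
        sex = rep(c("male", "female", "both"), each = length(years)),
        year = rep(years, 3),
        value = c(inv_transform(f_m, def$transform),
                  inv_transform(f_f, def$transform),
                  inv_transform((f_m + f_f) / 2, def$transform)),
        stringsAsFactors = FALSE)
    }
    ind_panel <- do.call(rbind, rows)
    if (spec$include_national) {
      f_nat_m <- colMeans(f_mat_m)
      f_nat_f <- colMeans(f_mat_f)
      ind_panel <- rbind(ind_panel, data.frame(
        location_id = "CN", region = "national",
        indicator_id = par$indicator_id,
        sex = rep(c("male", "female", "both"), each = length(years)),
        year = rep(years, 3),
        value = c(inv_transform(f_nat_m, def$transform),
                  inv_transform(f_nat_f, def$transform),
                  inv_transform((f_nat_m + f_nat_f) / 2, def$transform)),
        stringsAsFactors = FALSE))
    }
    out[[k]] <- ind_panel
  }
  panel <- do.call(rbind, out)
  rownames(panel) <- NULL
  validate_panel(panel, registry)
}

#' Construct a panel with a designed national achievement count
#'
#' Builds a deterministic (noise-free) panel whose full pipeline run --
#' anchor resolution, scaling, recency-weighted projection to each
#' indicator's target year, 90-point threshold -- yields exactly
#' `n_achieved` achieved indicators for the national location. Achieved
#' indicators are designed to land at a projected score of about 97,
#' non-achieved ones at about 55; the designed series are solved against the
#' package's own anchor-resolution and projection rules by root finding, and
#' the count is verified end-to-end before returning.
#'
#' @param n_achieved integer in \[0, 28\].
#' @param seed integer seed controlling which indicators are achieved and
#'   the province offsets.
#' @param registry registry data frame.
#' @param n_provinces provinces to include alongside the national series.
#' @return A validated panel data frame.
#' @export
make_achievement_scenario <- function(n_achieved, seed,
                                      registry = sdg_registry(),
                                      n_provinces = 31L) {
  if (n_achieved < 0 || n_achieved > nrow(registry)) {
    stop("n_achieved must lie in [0, ", nrow(registry), "]", call. = FALSE)
  }
  set.seed(seed)
  ids <- sample(registry$indicator_id)
  achieved <- ids[seq_len(n_achieved)]
  years <- 1990:2016
  params <- default_indicator_params()
  regions <- scenario_regions(n_provinces)
  prov_ids <- sprintf("P%02d", seq_len(n_provinces))
  prov_offsets <- stats::rnorm(n_provinces, 0, 0.05)

  out <- vector("list", nrow(registry))
  for (k in seq_len(nrow(registry))) {
    def <- registry[k, ]
    target_score <- if (def$indicator_id %in% achieved) 97 else 55
    base <- params$baseline[params$indicator_id == def$indicator_id]
    # a designable series must start on the unfavourable side of an
    # absolute target
    if (def$target_type == "absolute") {
      if (def$direction == "lower_better" && base <= def$target_value) {
        base <- if (def$transform == "logit")
          min(0.9, def$target_value * 2.5) else def$target_value * 2.5
      }
      if (def$direction == "higher_better" && base >= def$target_value) {
        base <- def$target_value / 2
      }
    }
    f_series <- solve_design_series(def, base, years, target_score)
    values_nat <- inv_transform(f_series, def$transform)
    rows <- list(data.frame(location_id = "CN", region = "national",
                            indicator_id = def$indicator_id, sex = "both",
                            year = years, value = values_nat,
                            stringsAsFactors = FALSE))
    scale_off <- if (def$transform == "linear") abs(base) * 0.02 else 1
    for (p in seq_len(n_provinces)) {
      rows[[p + 1]] <- data.frame(
        location_id = prov_ids[p], region = regions[p],
        indicator_id = def$indicator_id, sex = "both", year = years,
        value = inv_transform(f_series + prov_offsets[p] * scale_off,
                              def$transform),
        stringsAsFactors = FALSE)
    }
    out[[k]] <- do.call(rbind, rows)
  }
  panel <- do.call(rbind, out)
  rownames(panel) <- NULL
  panel <- validate_panel(panel, registry)

  got <- national_achievement(panel, registry)
  if (got != n_achieved) {
    stop("achievement scenario infeasible: designed ", n_achieved,
         ", pipeline yields ", got, call. = FALSE)
  }
  panel
}

# Design a transform-space series over `years` whose projected score at the
# indicator's target year equals `target_score`, given the package's own
# anchoring and projection rules. Monotone-trend series solve a slope by
# root finding; no-increase indicators that must fail use a V shape
# (improvement then reversal) so the worst anchor stays distinct from the
# 2015 baseline target.
solve_design_series <- function(def, baseline, years, target_score) {
  f0 <- apply_transform(baseline, def$transform)
  good_sign <- if (def$direction == "lower_better") -1 else 1
  v_shape <- def$target_type == "no_increase" && target_score < 90

  # a no-increase target resolves to the 2015 value, so any steadily
  # improving series scores beyond 100 (clipped) at the horizon: achieved by
  # construction, no solving needed
  if (def$target_type == "no_increase" && target_score >= 90) {
    t <- years - min(years)
    return(f0 + good_sign * 0.02 * t)
  }

  series_for <- function(theta) {
    t <- years - min(years)
    if (v_shape) {
      # improve at a fixed clip until 2010, then reverse at rate theta
      brk <- 2010 - min(years)
      down <- good_sign * 0.03
      f0 + ifelse(t <= brk, down * t, down * brk - good_sign * theta *
                    (t - brk))
    } else {
      f0 + good_sign * theta * t
    }
  }
  score_for <- function(theta) {
    f_series <- series_for(theta)
    values <- inv_transform(f_series, def$transform)
    hist <- years <= 2015
    tryCatch({
      anchors <- resolve_anchors(values[hist], years[hist], def)
      fit <- aroc_fit(values, years, def$transform)
      xh <- predict(fit, years = def$target_year)
      scale_value(unname(xh), anchors, clip = FALSE)
    }, error = function(e) {
      # a steep trial slope can collapse the worst anchor onto the resolved
      # target (degenerate anchors); saturate low so the root search can
      # bracket
      -200
    })
  }
  obj <- function(theta) score_for(theta) - target_score
  lo <- 1e-6
  hi <- if (v_shape) 0.1 else 0.25
  f_lo <- obj(lo)
  f_hi <- obj(hi)
  # expand until the objective brackets a root (the score may be increasing
  # or, for the V-shaped reversal, decreasing in theta)
  while (sign(f_lo) == sign(f_hi) && hi < 8 && !v_shape) {
    hi <- hi * 2
    f_hi <- obj(hi)
  }
  if (sign(f_lo) == sign(f_hi)) {
    stop("cannot design series for ", def$indicator_id,
         " at score ", target_score, call. = FALSE)
  }
  theta <- stats::uniroot(obj, c(lo, hi), f.lower = f_lo, f.upper = f_hi,
                          tol = 1e-10)$root
  series_for(theta)
}

# run the scale -> project -> threshold pipeline for the national location
# and count achieved indicators at their target years
national_achievement <- function(panel, registry, threshold = 90) {
  nat <- panel[panel$region == "national" & panel$sex == "both", ]
  scores <- numeric(0)
  for (id in unique(nat$indicator_id)) {
    def <- registry_row(registry, id)
    s <- nat[nat$indicator_id == id, ]
    hist <- s$year <= 2015
    anchors <- resolve_anchors(s$value[hist], s$year[hist], def)
    fit <- aroc_fit(s$value, s$year, def$transform)
    xh <- predict(fit, years = def$target_year)
    scores[id] <- scale_value(unname(xh), anchors)
  }
  count_achieved(scores, threshold)
}
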