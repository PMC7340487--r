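#' Annual changes of a series in transform space
#'
#' Computes `r_t = f(x_t) - f(x_{t-1})` for consecutive years, with `f` the
#' indicator transform (log-ratios for rates). Interior gaps of up to 5
#' consecutive missing years are filled by linear interpolation in transform
#' space before differencing; longer gaps are an error.
#'
#' @param values numeric series values in indicator units.
#' @param years matching calendar years (need not be sorted).
#' @param transform `"log"`, `"logit"` or `"linear"`.
#' @return Numeric vector of per-year changes, named by the later year of
#'   each pair.
#' @export
#' @examples
#' annual_changes(c(100, 90, 81), 2000:2002, "log")  # both ~ log(0.9)
annual_changes <- function(values, years, transform = "linear") {
  s <- regularize_series(values, years, transform)
  r <- diff(s$f_values)
  names(r) <- s$years[-1]
  r
}

# sort, validate domain, interpolate interior gaps in transform space;
# returns list(years, values, f_values, interpolated)
regularize_series <- function(values, years, transform,
                              max_gap = 5L) {
  stopifnot(length(values) == length(years))
  keep <- !is.na(values)
  values <- values[keep]
  years <- years[keep]
  o <- order(years)
  years <- as.integer(years[o])
  values <- as.numeric(values[o])
  if (anyDuplicated(years)) {
    stop("duplicate years in series", call. = FALSE)
  }
  if (length(years) < 2) {
    stop("series needs at least 2 years", call. = FALSE)
  }
  if (transform == "log" && any(values <= 0, na.rm = TRUE)) {
    pos <- values[!is.na(values) & values > 0]
    if (!length(pos)) stop("all-zero series under log transform",
                           call. = FALSE)
    values[!is.na(values) & values <= 0] <- min(pos) / 2
  }
  if (!all(in_transform_domain(values[!is.na(values)], transform))) {
    stop("series value outside ", transform, " domain", call. = FALSE)
  }
  full_years <- seq(years[1], years[length(years)])
  gap_runs <- rle(!full_years %in% years)
  if (any(gap_runs$lengths[gap_runs$values] > max_gap)) {
    stop("gap of more than ", max_gap, " consecutive missing years",
         call. = FALSE)
  }
  f_obs <- apply_transform(values, transform)
  f_full <- stats::approx(years, f_obs, xout = full_years)$y
  list(years = full_years,
       values = inv_transform(f_full, transform),
       f_values = f_full,
       interpolated = !full_years %in% years)
}

#' Recency weights for annual changes
#'
#' Weight proportional to `(t - first_year + 1)^omega`, normalised to sum to
#' one. `omega = 0` gives uniform weights; larger `omega` concentrates
#' weight on recent years.
#'
#' @param years vector of calendar years the weights refer to.
#' @param omega non-negative recency exponent.
#' @return Numeric weights summing to 1, in the order of sorted years.
#' @export
#' @examples
#' recency_weights(2001:2003, 1)  # 1/6, 2/6, 3/6
recency_weights <- function(years, omega) {
  if (omega < 0) stop("omega must be non-negative", call. = FALSE)
  years <- sort(as.integer(years))
  w <- (years - years[1] + 1)^omega
  w / sum(w)
}

#' Weighted mean annual rate of change
#'
#' @param changes numeric vector of annual changes in transform space.
#' @param weights matching weights (will not be re-normalised).
#' @return The scalar rate `sum(weights * changes)`.
#' @export
weighted_aroc <- function(changes, weights) {
  if (length(changes) != length(weights)) {
    stop("changes and weights must have equal length", call. = FALSE)
  }
  sum(weights * changes)
}

#' Select the recency exponent for one series
#'
#' Chooses `omega` from a grid by backcast validation: the model is fitted
#' on the series with the final `holdout_years` years held out, those years
#' are predicted, and the `omega` minimising the mean absolute error on the
#' natural scale wins. Ties break toward the smallest `omega`, so an exactly
#' constant-rate series selects the first grid value. Series too short to
#' hold out return `omega = 1` with a warning.
#'
#' @inheritParams annual_changes
#' @param omega_grid ascending candidate exponents, default
#'   `seq(0, 3, by = 0.25)`.
#' @param holdout_years number of final years held out, default 3.
#' @return The selected `omega`.
#' @export
select_omega <- function(values, years, transform = "linear",
                         omega_grid = seq(0, 3, by = 0.25),
                         holdout_years = 3L) {
  omega_grid <- sort(omega_grid)
  s <- regularize_series(values, years, transform)
  n <- length(s$years)
  if (n <= holdout_years + 2L) {
    warning("series too short for backcast selection; falling back to ",
            "omega = 1", call. = FALSE)
    return(1)
  }
  fit_idx <- seq_len(n - holdout_years)
  hold_idx <- seq(n - holdout_years + 1L, n)
  f_fit <- s$f_values[fit_idx]
  yr_fit <- s$years[fit_idx]
  changes <- diff(f_fit)
  last_f <- f_fit[length(f_fit)]
  last_yr <- yr_fit[length(yr_fit)]
  h <- s$years[hold_idx] - last_yr
  truth <- s$values[hold_idx]

  mae <- vapply(omega_grid, function(om) {
    w <- recency_weights(yr_fit[-1], om)
    rate <- weighted_aroc(changes, w)
    pred <- inv_transform(last_f + h * rate, transform)
    mean(abs(pred - truth))
  }, numeric(1))
  omega_grid[which.min(mae)]
}

#' Fit a recency-weighted annual-rate-of-change model to one series
#'
#' The model assumes the series drifts linearly in transform space (log for
#' rates, logit for proportions): the drift estimate is the recency-weighted
#' mean of the observed year-over-year changes, with weights
#' `(t - first_year + 1)^omega`. When `omega` is not given it is selected
#' per series by backcast validation on a grid (see [select_omega()]).
#'
#' @inheritParams select_omega
#' @param omega fixed recency exponent; `NULL` (default) selects from
#'   `omega_grid`.
#' @return An object of class `"sdg_aroc"` with components `rate` (drift per
#'   year in transform space), `omega`, `changes`, `weights`, `years`,
#'   `values`, `transform`, and bookkeeping fields. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()`,
#'   `simulate()` and `plot()`.
#' @export
#' @examples
#' fit <- aroc_fit(c(100, 90, 81), 2000:2002, transform = "log")
#' coef(fit)
#' predict(fit, years = 2004)  # 65.61 = 81 * 0.9^2
aroc_fit <- function(values, years, transform = "linear", omega = NULL,
                     omega_grid = seq(0, 3, by = 0.25), holdout_years = 3L) {
  s <- regularize_series(values, years, transform)
  if (is.null(omega)) {
    omega <- select_omega(s$values, s$years, transform, omega_grid,
                          holdout_years)
  }
  changes <- diff(s$f_values)
  weights <- recency_weights(s$years[-1], omega)
  rate <- weighted_aroc(changes, weights)
  structure(list(rate = rate,
                 omega = omega,
                 omega_grid = omega_grid,
                 holdout_years = holdout_years,
                 changes = changes,
                 weights = weights,
                 years = s$years,
                 values = s$values,
                 f_values = s$f_values,
                 interpolated = s$interpolated,
                 transform = transform,
                 call = match.call()),
            class = "sdg_aroc")
}

#' @export
print.sdg_aroc <- function(x, ...) {
  cat("Recency-weighted annual rate of change model\n")
  cat("  transform:", x$transform, "  years:", x$years[1], "-",
      x$years[length(x$years)], "\n")
  cat("  omega:", format(x$omega), "  rate:", format(x$rate, digits = 6),
      "per year (transform space)\n")
  invisible(x)
}

#' @export
summary.sdg_aroc <- function(object, ...) {
  res <- stats::residuals(object)
  out <- list(rate = object$rate, omega = object$omega,
              transform = object$transform,
              n_years = length(object$years),
              n_interpolated = sum(object$interpolated),
              sigma = stats::sd(res),
              pct_per_year = if (object$transform == "log")
                100 * (exp(object$rate) - 1) else NA_real_)
  class(out) <- "summary.sdg_aroc"
  out
}

#' @export
print.summary.sdg_aroc <- function(x, ...) {
  cat("Recency-weighted AROC fit (", x$transform, " space)\n", sep = "")
  cat("  years fitted:       ", x$n_years,
      if (x$n_interpolated) paste0(" (", x$n_interpolated, " interpolated)"),
      "\n", sep = "")
  cat("  omega:              ", format(x$omega), "\n", sep = "")
  cat("  drift per year:     ", format(x$rate, digits = 6), "\n", sep = "")
  if (!is.na(x$pct_per_year)) {
    cat("  equivalent % change:", sprintf("%+.2f%% per year", x$pct_per_year),
        "\n")
  }
  cat("  residual sd:        ", format(x$sigma, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.sdg_aroc <- function(object, ...) {
  c(rate = object$rate, omega = object$omega)
}

#' Project a fitted series forward
#'
#' Extrapolates `f(x_{T+h}) = f(x_T) + h * rate` and back-transforms, so
#' projections of log-scaled indicators stay positive and logit-scaled ones
#' stay inside (0, 1).
#'
#' @param object an `"sdg_aroc"` fit.
#' @param years calendar years to predict (default: the year after the last
#'   observation through `horizon_year` if given).
#' @param horizon_year convenience alternative to `years`.
#' @param ... unused.
#' @return Named numeric vector of projected values in indicator units.
#' @export
predict.sdg_aroc <- function(object, years = NULL, horizon_year = NULL, ...) {
  last_yr <- object$years[length(object$years)]
  if (is.null(years)) {
    if (is.null(horizon_year)) {
      stop("supply 'years' or 'horizon_year'", call. = FALSE)
    }
    if (horizon_year <= last_yr) {
      stop("horizon_year must be after the last observed year (", last_yr,
           ")", call. = FALSE)
    }
    years <- seq(last_yr + 1L, horizon_year)
  }
  h <- years - last_yr
  f_last <- object$f_values[length(object$f_values)]
  out <- inv_transform(f_last + h * object$rate, object$transform)
  names(out) <- years
  out
}

#' @export
fitted.sdg_aroc <- function(object, ...) {
  # one-step-ahead fitted values under the constant-drift model
  f_prev <- object$f_values[-length(object$f_values)]
  out <- c(object$values[1],
           inv_transform(f_prev + object$rate, object$transform))
  names(out) <- object$years
  out
}

#' @export
residuals.sdg_aroc <- function(object, ...) {
  # transform-space one-step residuals: observed change minus fitted drift
  res <- object$changes - object$rate
  names(res) <- object$years[-1]
  res
}

#' Simulate series from a fitted AROC model
#'
#' Draws series of the same length as the data: the first value is kept
#' fixed and transform-space increments are `rate + N(0, sigma^2)`, with
#' `sigma` the fitted residual standard deviation (overridable).
#'
#' @param object an `"sdg_aroc"` fit.
#' @param nsim number of series to simulate.
#' @param seed optional seed, handled as in [stats::simulate()].
#' @param sigma innovation standard deviation; default the residual sd.
#' @param ... unused.
#' @return A data frame with one column per simulated series, row-named by
#'   year.
#' @export
simulate.sdg_aroc <- function(object, nsim = 1, seed = NULL,
                              sigma = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma)) sigma <- stats::sd(stats::residuals(object))
  n <- length(object$years)
  sims <- vapply(seq_len(nsim), function(k) {
    eps <- stats::rnorm(n - 1, mean = object$rate, sd = sigma)
    inv_transform(object$f_values[1] + c(0, cumsum(eps)), object$transform)
  }, numeric(n))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$years
  out
}

#' @export
plot.sdg_aroc <- function(x, horizon_year = NULL, ...) {
  yrs <- x$years
  vals <- x$values
  if (!is.null(horizon_year) && horizon_year > yrs[length(yrs)]) {
    proj <- predict(x, horizon_year = horizon_year)
    plot(yrs, vals, type = "b", pch = 16,
         xlim = c(yrs[1], horizon_year),
         ylim = range(c(vals, proj)),
         xlab = "year", ylab = "value", ...)
    lines(as.integer(names(proj)), proj, lty = 2, col = "grey40")
    points(as.integer(names(proj)), proj, pch = 1, col = "grey40")
  } else {
    plot(yrs, vals, type = "b", pch = 16, xlab = "year", ylab = "value", ...)
  }
  invisible(x)
}

#' Project one series to a horizon year
#'
#' Convenience wrapper around [aroc_fit()] + [predict()]: fits the model and
#' returns the yearly projected path from the year after the last
#' observation through `horizon_year`.
#'
#' @inheritParams aroc_fit
#' @param horizon_year target calendar year, after the last observed year.
#' @return A data frame with columns `year`, `value`, and attributes
#'   `omega` and `rate`.
#' @export
project_series <- function(values, years, transform = "linear",
                           horizon_year, omega = NULL,
                           omega_grid = seq(0, 3, by = 0.25),
                           holdout_years = 3L) {
  fit <- aroc_fit(values, years, transform, omega, omega_grid, holdout_years)
  pred <- predict(fit, horizon_year = horizon_year)
  out <- data.frame(year = as.integer(names(pred)), value = unname(pred))
  attr(out, "omega") <- fit$omega
  attr(out, "rate") <- fit$rate
  out
}

#' Project every series of a panel
#'
#' Fits a recency-weighted AROC model per (location, indicator, sex) series
#' and emits the projected yearly path from the year after the series' last
#' observation through `horizon`. Sex-specific absolute values are projected
#' independently. Failing series are dropped with a summarising warning.
#'
#' @param panel a validated panel data frame.
#' @param registry registry data frame (provides the transform per
#'   indicator).
#' @param omega_grid candidate recency exponents.
#' @param holdout_years backcast holdout length for omega selection.
#' @param horizon last projected calendar year, default 2030.
#' @return A panel-shaped data frame of projected records with an extra
#'   `omega` column.
#' @export
project_panel <- function(panel, registry = sdg_registry(),
                          omega_grid = seq(0, 3, by = 0.25),
                          holdout_years = 3L, horizon = 2030L) {
  panel <- validate_panel(panel, registry)
  parts <- split(panel,
                 list(panel$location_id, panel$indicator_id, panel$sex),
                 drop = TRUE)
  failures <- character(0)
  out <- lapply(parts, function(s) {
    def <- registry_row(registry, s$indicator_id[1])
    tryCatch({
      pr <- project_series(s$value, s$year, def$transform,
                           horizon_year = horizon,
                           omega_grid = omega_grid,
                           holdout_years = holdout_years)
      data.frame(location_id = s$location_id[1],
                 region = s$region[1],
                 indicator_id = s$indicator_id[1],
                 sex = s$sex[1],
                 year = pr$year,
                 value = pr$value,
                 omega = attr(pr, "omega"),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<- paste0(
        "(", s$location_id[1], ", ", s$indicator_id[1], ", ", s$sex[1],
        "): ", conditionMessage(e))
      NULL
    })
  })
  if (length(failures)) {
    warning(length(failures), " series could not be projected:\n  ",
            paste(utils::head(failures, 5), collapse = "\n  "),
            if (length(failures) > 5) "\n  ..." else "", call. = FALSE)
  }
  out <- do.call(rbind, Filter(Negate(is.null), out))
  rownames(out) <- NULL
  out[order(out$location_id, out$indicator_id, out$sex, out$year), ]
}
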