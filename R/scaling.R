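#' Flag outliers by Tukey fences
#'
#' Marks values falling outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, the rule used
#' to trim historical extremes before the worst-value anchor is taken.
#' Quartiles are computed by linear interpolation between order statistics
#' (`stats::quantile()` type 7). The mask is computed in a single pass; it is
#' not iterated on the retained values.
#'
#' @param values numeric vector, at least 4 values.
#' @return Logical vector, `TRUE` where the value is an outlier.
#' @export
#' @examples
#' tukey_outliers(c(1, 2, 3, 4, 100))  # only 100 flagged
tukey_outliers <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4 || anyNA(values)) {
    stop("tukey_outliers needs at least 4 non-missing values", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
}

#' Resolve the 0 and 100 anchors for one indicator series
#'
#' The attainment index maps the worst outlier-trimmed value observed over
#' the anchor window (1990-2015 by default) to 0 and the resolved target to
#' 100. "Worst" is the maximum retained value for `lower_better` indicators
#' and the minimum for `higher_better` ones. The target is resolved from the
#' indicator definition:
#' \describe{
#'   \item{absolute}{the registered `target_value` in indicator units;}
#'   \item{relative_reduction}{the value observed in `baseline_year` times
#'     `1 - target_value`;}
#'   \item{no_increase}{the value observed in `baseline_year`;}
#'   \item{elimination}{half the smallest positive retained value, the same
#'     floor convention used for exact zeros under log/logit scaling.}
#' }
#'
#' @param values numeric series values in indicator units.
#' @param years matching calendar years.
#' @param definition one registry row (see [sdg_registry()]).
#' @param anchor_window two-element year range used for anchoring, default
#'   `c(1990, 2015)`.
#' @return An object of class `"sdg_anchors"`: a list with `worst`, `target`,
#'   `transform`, `direction`, `zero_floor`, `inverted` (`TRUE` when even the
#'   worst retained value already meets an absolute target, so the indicator
#'   is graded pass/fail) and `window`.
#' @export
resolve_anchors <- function(values, years, definition,
                            anchor_window = c(1990L, 2015L)) {
  stopifnot(length(values) == length(years))
  keep <- years >= anchor_window[1] & years <= anchor_window[2] &
    !is.na(values)
  v <- values[keep]
  yr <- years[keep]
  if (length(v) < 4) {
    stop("insufficient data to anchor indicator ", definition$indicator_id,
         ": need >= 4 values within ", anchor_window[1], "-",
         anchor_window[2], call. = FALSE)
  }
  retained <- v[!tukey_outliers(v)]

  positive <- retained[retained > 0]
  zero_floor <- if (length(positive)) min(positive) / 2 else NA_real_

  worst <- if (definition$direction == "lower_better") max(retained)
           else min(retained)

  target <- switch(definition$target_type,
    absolute = definition$target_value,
    relative_reduction = {
      base <- value_at_year(v, yr, definition$baseline_year)
      base * (1 - definition$target_value)
    },
    no_increase = value_at_year(v, yr, definition$baseline_year),
    elimination = {
      if (is.na(zero_floor)) {
        stop("cannot resolve elimination target for ",
             definition$indicator_id, ": no positive values", call. = FALSE)
      }
      zero_floor
    },
    stop("unknown target_type: ", definition$target_type, call. = FALSE)
  )

  if (definition$transform == "log" && worst <= 0) worst <- zero_floor
  if (definition$transform == "log" && target <= 0) target <- zero_floor

  if (all(vapply(retained, function(z) isTRUE(all.equal(z, target)),
                 logical(1)))) {
    stop("degenerate anchors for ", definition$indicator_id,
         ": every retained value equals the resolved target (",
         format(target), ")", call. = FALSE)
  }
  # If even the worst retained historical value meets the target -- a fixed
  # absolute target the series always satisfied (childhood wasting under its
  # 5% ceiling), or a no-increase baseline that happens to be the historical
  # maximum -- there is no unfavourable span to stretch a 0-100 scale over:
  # the indicator is graded pass/fail against the target (see scale_value).
  inverted <- if (definition$direction == "lower_better") worst <= target
              else worst >= target

  structure(list(worst = worst, target = target,
                 transform = definition$transform,
                 direction = definition$direction,
                 zero_floor = zero_floor,
                 inverted = inverted,
                 window = anchor_window),
            class = "sdg_anchors")
}

# baseline lookup: exact year if observed, otherwise the nearest observed
# year (with a warning), ties toward the earlier year
value_at_year <- function(values, years, year) {
  k <- match(year, years)
  if (is.na(k)) {
    d <- abs(years - year)
    k <- which(d == min(d))[1]
    warning("baseline year ", year, " not observed; using nearest year ",
            years[k], call. = FALSE)
  }
  values[k]
}

#' Scale a value to the 0-100 attainment index
#'
#' Computes `100 * (f(x) - f(worst)) / (f(target) - f(worst))` with `f` the
#' indicator's transform (log for rates, logit for proportions, identity
#' otherwise), clipped to \[0, 100\]: values at or beyond the target score
#' 100, values at or beyond the worst anchor score 0. Exact zeros under a
#' log transform are replaced by the anchor's series floor (half the
#' smallest positive retained value) before scaling, which lets elimination
#' successes score 100 after clipping. Inverted anchors (the whole trimmed
#' history already meets an absolute target) grade pass/fail: 100 where the
#' value meets the target, 0 where it has deteriorated past it.
#'
#' @param x numeric value(s) in indicator units.
#' @param anchors an `"sdg_anchors"` object from [resolve_anchors()].
#' @param clip clip the result to \[0, 100\] (default). Unclipped scores are
#'   occasionally useful for diagnostics.
#' @return Numeric score(s).
#' @export
#' @examples
#' a <- structure(list(worst = 100, target = 1, transform = "log",
#'                     direction = "lower_better", zero_floor = 0.5,
#'                     window = c(1990L, 2015L)), class = "sdg_anchors")
#' scale_value(10, a)  # geometric midpoint -> 50
scale_value <- function(x, anchors, clip = TRUE) {
  stopifnot(inherits(anchors, "sdg_anchors"))
  if (anchors$transform == "log") {
    x[!is.na(x) & x <= 0] <- anchors$zero_floor
  }
  if (any(!is.finite(x))) {
    stop("non-finite value passed to scale_value", call. = FALSE)
  }
  if (!all(in_transform_domain(x, anchors$transform))) {
    stop("value outside ", anchors$transform, " domain in scale_value",
         call. = FALSE)
  }
  if (isTRUE(anchors$inverted)) {
    meets <- if (anchors$direction == "lower_better") x <= anchors$target
             else x >= anchors$target
    return(ifelse(meets, 100, 0))
  }
  f <- function(z) apply_transform(z, anchors$transform)
  denom <- f(anchors$target) - f(anchors$worst)
  if (!is.finite(denom) || denom == 0) {
    stop("degenerate anchors in scale_value", call. = FALSE)
  }
  score <- 100 * (f(x) - f(anchors$worst)) / denom
  if (clip) score <- pmin(100, pmax(0, score))
  score
}

#' Scale a whole panel to attainment scores
#'
#' Resolves anchors for every (location, indicator, sex) series from that
#' series' own history inside the anchor window, then scores every record.
#' With `anchor_level = "national"` all locations are scored against the
#' anchors of the national series (the panel must contain a location with
#' region `"national"`).
#'
#' Series whose anchors cannot be resolved (too short, degenerate) are
#' dropped with a single summarising warning; all other series are scored.
#'
#' @param panel a validated panel data frame (see [read_panel()]).
#' @param registry registry data frame.
#' @param anchor_level `"location"` (default) or `"national"`.
#' @param anchor_window two-element year range, default `c(1990, 2015)`.
#' @return A data frame: panel columns plus `score`, `worst`, `target`.
#' @export
scale_panel <- function(panel, registry = sdg_registry(),
                        anchor_level = c("location", "national"),
                        anchor_window = c(1990L, 2015L)) {
  anchor_level <- match.arg(anchor_level)
  panel <- validate_panel(panel, registry)

  national_ids <- unique(panel$location_id[panel$region == "national"])
  if (anchor_level == "national" && length(national_ids) != 1) {
    stop("anchor_level = 'national' needs exactly one location with region ",
         "'national' in the panel", call. = FALSE)
  }

  parts <- split(panel,
                 list(panel$location_id, panel$indicator_id, panel$sex),
                 drop = TRUE)
  failures <- character(0)
  out <- lapply(parts, function(s) {
    def <- registry_row(registry, s$indicator_id[1])
    anchor_src <- s
    if (anchor_level == "national") {
      anchor_src <- panel[panel$location_id == national_ids &
                          panel$indicator_id == s$indicator_id[1] &
                          panel$sex == s$sex[1], ]
    }
    res <- tryCatch({
      anchors <- resolve_anchors(anchor_src$value, anchor_src$year, def,
                                 anchor_window)
      s$score <- scale_value(s$value, anchors)
      s$worst <- anchors$worst
      s$target <- anchors$target
      s
    }, error = function(e) {
      failures[[length(failures) + 1L]] <<- paste0(
        "(", s$location_id[1], ", ", s$indicator_id[1], ", ", s$sex[1],
        "): ", conditionMessage(e))
      NULL
    })
    res
  })
  if (length(failures)) {
    warning(length(failures), " series could not be scored and were ",
            "dropped:\n  ", paste(utils::head(failures, 5), collapse = "\n  "),
            if (length(failures) > 5) "\n  ..." else "", call. = FALSE)
  }
  out <- do.call(rbind, Filter(Negate(is.null), out))
  rownames(out) <- NULL
  out[order(out$location_id, out$indicator_id, out$sex, out$year), ]
}
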