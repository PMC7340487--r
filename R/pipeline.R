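#' Run the full attainment pipeline on a panel
#'
#' Orchestrates the whole analysis: every (location, indicator, sex) series
#' is projected to `horizon` with a recency-weighted AROC model, the
#' observed and projected values are rescaled to 0-100 attainment scores
#' against anchors resolved from the observed history, scores are aggregated
#' into thematic-topic indices, and achievement is counted per location at
#' each indicator's target year against the threshold.
#'
#' @param panel a validated panel of observed values (see [read_panel()],
#'   [generate_panel()]).
#' @param registry registry data frame.
#' @param omega_grid candidate recency exponents.
#' @param holdout_years backcast holdout for omega selection.
#' @param threshold achievement threshold on the attainment index,
#'   default 90.
#' @param anchor_level `"location"` or `"national"` (see [scale_panel()]).
#' @param horizon last projected year, default 2030.
#' @return An object of class `"sdg_pipeline"`: a list with `scores`,
#'   `topic_indices`, `projections`, `progress` (per-location achieved
#'   counts and per-topic annual change rates), and `manifest` (the run
#'   parameters; identical manifests reproduce identical outputs).
#' @export
sdg_pipeline <- function(panel, registry = sdg_registry(),
                         omega_grid = seq(0, 3, by = 0.25),
                         holdout_years = 3L, threshold = 90,
                         anchor_level = c("location", "national"),
                         horizon = 2030L) {
  anchor_level <- match.arg(anchor_level)
  panel <- validate_panel(panel, registry)
  last_observed <- max(panel$year)

  projections <- project_panel(panel, registry, omega_grid, holdout_years,
                               horizon)
  combined <- rbind(panel[, c("location_id", "region", "indicator_id",
                              "sex", "year", "value")],
                    projections[, c("location_id", "region", "indicator_id",
                                    "sex", "year", "value")])
  scores <- scale_panel(combined, registry, anchor_level)
  topic_indices <- aggregate_topics(scores, registry)

  progress <- pipeline_progress(scores, topic_indices, registry,
                                threshold, last_observed)

  manifest <- list(n_records = nrow(panel),
                   locations = sort(unique(panel$location_id)),
                   indicators = sort(unique(panel$indicator_id)),
                   years = range(panel$year),
                   omega_grid = omega_grid,
                   holdout_years = holdout_years,
                   threshold = threshold,
                   anchor_level = anchor_level,
                   horizon = horizon)

  structure(list(scores = scores, topic_indices = topic_indices,
                 projections = projections, progress = progress,
                 manifest = manifest),
            class = "sdg_pipeline")
}

# per-location achieved counts (both-sex scores at each indicator's target
# year) and per-topic annual change rates from the last observed year to the
# topic horizon (the latest member target year)
pipeline_progress <- function(scores, topic_indices, registry, threshold,
                              last_observed) {
  members <- topic_members(registry)
  topic_horizon <- vapply(members, function(ids) {
    max(registry$target_year[registry$indicator_id %in% ids])
  }, numeric(1))

  achieved <- lapply(split(scores[scores$sex == "both", ],
                           scores$location_id[scores$sex == "both"]),
                     function(s) {
    at_target <- vapply(unique(s$indicator_id), function(id) {
      ty <- registry$target_year[registry$indicator_id == id]
      v <- s$score[s$indicator_id == id & s$year == ty]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
    data.frame(location_id = s$location_id[1],
               region = s$region[1],
               n_achieved = suppressWarnings(count_achieved(at_target,
                                                            threshold)),
               n_total = length(at_target),
               stringsAsFactors = FALSE)
  })
  achieved <- do.call(rbind, achieved)
  rownames(achieved) <- NULL

  ti <- topic_indices[topic_indices$sex == "both", ]
  rates <- lapply(split(ti, list(ti$location_id, ti$topic), drop = TRUE),
                  function(s) {
    hy <- topic_horizon[[s$topic[1]]]
    i0 <- s$index[s$year == last_observed]
    i1 <- s$index[s$year == hy]
    if (!length(i0) || !length(i1)) return(NULL)
    data.frame(location_id = s$location_id[1], topic = s$topic[1],
               index_start = i0, index_end = i1,
               year_start = last_observed, year_end = hy,
               annual_change = annual_change_rate(i0, i1, last_observed, hy),
               stringsAsFactors = FALSE)
  })
  rates <- do.call(rbind, Filter(Negate(is.null), rates))
  rownames(rates) <- NULL
  list(achievement = achieved[order(achieved$location_id), ],
       topic_rates = rates[order(rates$location_id, rates$topic), ])
}

#' @export
print.sdg_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("SDG attainment pipeline run\n")
  cat("  locations: ", length(m$locations), "   indicators: ",
      length(m$indicators), "   observed years: ", m$years[1], "-",
      m$years[2], "\n", sep = "")
  cat("  projected through ", m$horizon, ", threshold ", m$threshold,
      ", anchors at ", m$anchor_level, " level\n", sep = "")
  nat <- x$progress$achievement[
    x$progress$achievement$region == "national", ]
  if (nrow(nat)) {
    cat("  national indicators achieved at target year: ", nat$n_achieved,
        " of ", nat$n_total, "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.sdg_pipeline <- function(object, ...) {
  nat_rates <- object$progress$topic_rates
  nat_ids <- unique(object$scores$location_id[
    object$scores$region == "national"])
  if (length(nat_ids)) {
    nat_rates <- nat_rates[nat_rates$location_id %in% nat_ids, ]
  }
  out <- list(manifest = object$manifest,
              achievement = object$progress$achievement,
              national_topics = nat_rates)
  class(out) <- "summary.sdg_pipeline"
  out
}

#' @export
print.summary.sdg_pipeline <- function(x, ...) {
  cat("Topic trajectories (index points):\n")
  df <- x$national_topics
  if (nrow(df)) {
    df$annual_change <- round(df$annual_change, 1)
    df$index_start <- round(df$index_start, 1)
    df$index_end <- round(df$index_end, 1)
    print(df[, c("location_id", "topic", "year_start", "index_start",
                 "year_end", "index_end", "annual_change")],
          row.names = FALSE)
  }
  cat("\nIndicators achieved per location:\n")
  print(utils::head(x$achievement, 12), row.names = FALSE)
  if (nrow(x$achievement) > 12) cat("  ...\n")
  invisible(x)
}
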