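#' Count indicators achieving the attainment threshold
#'
#' An indicator counts as achieved when its attainment score at the target
#' year is at or above the threshold (90 by default; the comparison is
#' inclusive).
#'
#' @param scores numeric vector of attainment scores at the target year, one
#'   per indicator (`NA`s are dropped with a warning).
#' @param threshold achievement threshold, default 90.
#' @return Integer count of achieved indicators.
#' @export
#' @examples
#' count_achieved(c(100, 89.9, 90))  # 2
count_achieved <- function(scores, threshold = 90) {
  scores <- as.numeric(scores)
  if (anyNA(scores)) {
    warning(sum(is.na(scores)), " missing score(s) dropped from achievement ",
            "count", call. = FALSE)
    scores <- scores[!is.na(scores)]
  }
  sum(scores >= threshold)
}

#' Annual change rate of an index between two years
#'
#' `(index_end - index_start) / (year_end - year_start)`, in index points
#' per year.
#'
#' @param index_start,index_end index values at the two endpoints.
#' @param year_start,year_end the two calendar years, `year_end` later.
#' @return Points per year.
#' @export
#' @examples
#' annual_change_rate(63.6, 70.0, 2016, 2020)  # 1.6
annual_change_rate <- function(index_start, index_end, year_start, year_end) {
  if (any(year_end <= year_start)) {
    stop("year_end must be after year_start", call. = FALSE)
  }
  (index_end - index_start) / (year_end - year_start)
}

#' Disparity ratio between two strata
#'
#' Simple ratio `value_a / value_b`, reported numerator over denominator in
#' the stated stratum order (e.g. rural/urban, male/female,
#' western/eastern); reciprocals are never auto-flipped.
#'
#' @param value_a numerator stratum value.
#' @param value_b denominator stratum value (> 0).
#' @return The ratio.
#' @export
#' @examples
#' disparity_ratio(12.4, 5.2)  # rural/urban under-5 mortality, ~2.4
disparity_ratio <- function(value_a, value_b) {
  if (any(value_b <= 0)) {
    stop("denominator stratum must be positive", call. = FALSE)
  }
  value_a / value_b
}

#' Regional summary of topic indices
#'
#' Unweighted per-region mean, minimum and maximum of topic indices across
#' provinces, for the eastern/central/western grouping. National aggregates
#' and Special Administrative Regions are excluded.
#'
#' @param topic_indices topic index table from [aggregate_topics()] (needs
#'   `region`, `topic`, `year`, `index`; `sex` is kept if present).
#' @return A data frame with one row per (region, topic, year\[, sex\]) and
#'   columns `mean`, `min`, `max`, `n_provinces`.
#' @export
regional_summary <- function(topic_indices) {
  stopifnot(all(c("region", "topic", "year", "index")
                %in% names(topic_indices)))
  df <- topic_indices[!topic_indices$region %in% c("national", "SAR"), ]
  if (any(is.na(df$region))) {
    stop("unmapped province(s): region is NA for ",
         paste(utils::head(unique(df$location_id[is.na(df$region)]), 5),
               collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$region), c("eastern", "central", "western"))
  if (length(bad)) {
    stop("unknown region(s) in topic indices: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  keys <- c("region", "topic", "year", intersect("sex", names(df)))
  parts <- split(df, df[keys], drop = TRUE)
  out <- lapply(parts, function(s) {
    cbind(s[1, keys, drop = FALSE],
          data.frame(mean = mean(s$index), min = min(s$index),
                     max = max(s$index),
                     n_provinces = length(unique(s$location_id))))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[do.call(order, out[keys]), ]
}
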