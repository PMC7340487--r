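#' Floored geometric mean of attainment scores
#'
#' Equal-weight geometric mean with scores below 1 raised to 1 first, so
#' that a single zero cannot annihilate a topic index. This is the
#' aggregation rule behind every thematic-topic index.
#'
#' @param scores numeric vector of scores in \[0, 100\].
#' @return A number in \[1, 100\].
#' @export
#' @examples
#' geomean_floored(c(40, 63, 100, 49, 80))
geomean_floored <- function(scores) {
  scores <- as.numeric(scores)
  scores <- scores[!is.na(scores)]
  if (!length(scores)) {
    stop("geomean_floored needs at least one score", call. = FALSE)
  }
  exp(mean(log(pmax(scores, 1))))
}

#' Aggregate indicator scores into thematic-topic indices
#'
#' One index per (location, sex, topic, year): the equal-weight floored
#' geometric mean of the member indicator scores present for that cell.
#' Cells missing some registered members are aggregated over the available
#' members; a single warning summarises how many cells were incomplete.
#' Flooring is applied to unrounded scores.
#'
#' @param scores score table from [scale_panel()] (needs columns
#'   `location_id`, `region`, `indicator_id`, `sex`, `year`, `score`).
#' @param registry registry data frame.
#' @return A data frame with columns `location_id`, `region`, `sex`,
#'   `topic`, `year`, `index`, `n_members`, `members` (semicolon-separated
#'   indicator ids).
#' @export
aggregate_topics <- function(scores, registry = sdg_registry()) {
  stopifnot(all(c("location_id", "indicator_id", "sex", "year", "score")
                %in% names(scores)))
  unknown <- setdiff(unique(scores$indicator_id), registry$indicator_id)
  if (length(unknown)) {
    stop("score table references indicator(s) not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  members <- topic_members(registry)
  scores$topic <- registry$topic[match(scores$indicator_id,
                                       registry$indicator_id)]
  if (!"region" %in% names(scores)) scores$region <- NA_character_

  parts <- split(scores,
                 list(scores$location_id, scores$sex, scores$topic,
                      scores$year),
                 drop = TRUE)
  incomplete <- 0L
  out <- lapply(parts, function(s) {
    topic <- s$topic[1]
    expected <- members[[topic]]
    if (length(unique(s$indicator_id)) < length(expected)) {
      incomplete <<- incomplete + 1L
    }
    data.frame(location_id = s$location_id[1],
               region = s$region[1],
               sex = s$sex[1],
               topic = topic,
               year = s$year[1],
               index = geomean_floored(s$score),
               n_members = length(unique(s$indicator_id)),
               members = paste(sort(unique(s$indicator_id)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  if (incomplete > 0L) {
    warning(incomplete, " topic cell(s) aggregated over fewer members than ",
            "the registry defines", call. = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$location_id, out$topic, out$sex, out$year), ]
}
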