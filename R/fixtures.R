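#' National 2016 attainment scores (published table transcription)
#'
#' The published national (China) attainment scores of the 28 indicators for
#' 2016, as printed (integers). Useful as a worked-example input for topic
#' aggregation and report writing without any external data.
#'
#' @return A data frame with columns `indicator_id`, `topic`, `year`,
#'   `score`, plus an attribute `"subtotals"` holding the printed per-topic
#'   subtotal integers.
#' @export
#' @examples
#' s <- fixture_national_scores()
#' s$score[s$topic == "infectious"]  # 40 63 100 49 80
fixture_national_scores <- function() {
  reg <- sdg_registry()
  score <- c(
    "2.2.1" = 86, "2.2.2a" = 100, "2.2.2b" = 94,
    "3.1.1" = 100, "3.1.2" = 92, "3.2.1" = 100, "3.2.2" = 100,
    "3.b.1" = 98, "3.7.1" = 66,
    "3.3.1" = 40, "3.3.2" = 63, "3.3.3" = 100, "3.3.4" = 49, "3.3.5" = 80,
    "3.4.1" = 72, "3.4.2" = 89,
    "3.a.1" = 74, "3.5.2" = 50,
    "3.6.1" = 64,
    "3.9.1" = 58, "3.9.2" = 95, "3.9.3" = 79,
    "11.6.2" = 31, "7.1.2" = 76, "6.1.1" = 56, "6.2.1a" = 72,
    "6.2.1b" = 66,
    "3.8.1" = 54)
  out <- data.frame(indicator_id = names(score),
                    topic = reg$topic[match(names(score), reg$indicator_id)],
                    year = 2016L,
                    score = unname(score),
                    stringsAsFactors = FALSE)
  attr(out, "subtotals") <- c(child_nutrition = 91, mchrh = 92,
                              infectious = 63, ncd_mortality = 80,
                              ncd_risk = 60, road_injury = 64,
                              env_outcome = 75, env_exposure = 55, uhc = 54)
  out
}

#' Published national topic indices and projections
#'
#' The published national thematic-topic attainment indices for 2016, the
#' projected index at each topic's horizon year and the published annual
#' change rate (index points per year). Several published rates are not
#' reproducible from the printed one-decimal endpoints (they were evidently
#' computed on unrounded series); the `endpoint_consistent` column flags the
#' topics where endpoint arithmetic reproduces the printed rate at one
#' decimal.
#'
#' @return A data frame with columns `topic`, `index_2016`, `horizon_year`,
#'   `index_horizon`, `printed_rate`, `endpoint_consistent`.
#' @export
fixture_topic_indices <- function() {
  out <- data.frame(
    topic = c("child_nutrition", "mchrh", "infectious", "ncd_mortality",
              "ncd_risk", "road_injury", "env_outcome", "env_exposure",
              "uhc"),
    index_2016 = c(91.1, 91.8, 63.0, 79.7, 60.5, 63.6, 75.5, 54.9, 54.4),
    horizon_year = c(2025L, 2030L, 2030L, 2030L, 2025L, 2020L, 2030L,
                     2030L, 2030L),
    index_horizon = c(80.5, 95.3, 73.8, 100.0, 38.8, 70.0, 89.2, 60.2,
                      69.2),
    printed_rate = c(-1.1, 1.0, 0.7, 1.6, -1.3, 1.6, 0.9, 0.4, 1.1),
    stringsAsFactors = FALSE)
  out$endpoint_consistent <- vapply(seq_len(nrow(out)), function(i) {
    r <- annual_change_rate(out$index_2016[i], out$index_horizon[i],
                            2016, out$horizon_year[i])
    isTRUE(all.equal(round(r, 1), out$printed_rate[i]))
  }, logical(1))
  out
}

#' Published stratified indicator values (survey/surveillance transcription)
#'
#' Sex-, residence- and total-stratified values of key indicators from the
#' published national surveillance tables: child nutrition (2002, 2013),
#' maternal and child mortality (2010, 2016), suicide (2013, 2016) and road
#' injury mortality (2010, 2015). Values are in the units of each measure
#' (percent for prevalences, per 1,000 or 100,000 for mortality).
#'
#' @return A data frame with columns `measure`, `indicator_id` (registry id
#'   where one applies), `stratum`, `year`, `value`.
#' @export
#' @examples
#' d <- fixture_disparities()
#' d$value[d$measure == "stunting" & d$stratum == "male" & d$year == 2013]
fixture_disparities <- function() {
  row <- function(measure, indicator_id, stratum, year, value) {
    data.frame(measure = measure, indicator_id = indicator_id,
               stratum = stratum, year = year, value = value,
               stringsAsFactors = FALSE)
  }
  strat6 <- function(measure, id, years, totals, male, female, urban,
                     rural) {
    do.call(rbind, list(
      row(measure, id, "total", years, totals),
      row(measure, id, "male", years, male),
      row(measure, id, "female", years, female),
      row(measure, id, "urban", years, urban),
      row(measure, id, "rural", years, rural)))
  }
  out <- rbind(
    strat6("stunting", "2.2.1", c(2002, 2013),
           totals = c(16.3, 8.1), male = c(17.1, 8.7),
           female = c(15.4, 7.4), urban = c(7.2, 4.2),
           rural = c(23.8, 11.3)),
    strat6("wasting", "2.2.2a", c(2002, 2013),
           totals = c(2.6, 2.0), male = c(2.8, 2.0), female = c(2.3, 2.0),
           urban = c(2.1, 2.4), rural = c(3.0, 1.5)),
    strat6("overweight", "2.2.2b", c(2002, 2013),
           totals = c(6.5, 8.4), male = c(7.3, 9.4), female = c(5.5, 7.2),
           urban = c(7.7, 8.4), rural = c(5.5, 8.4)),
    rbind(row("mmr", "3.1.1", "total", c(2010, 2016), c(30.0, 19.9)),
          row("mmr", "3.1.1", "urban", c(2010, 2016), c(29.7, 19.5)),
          row("mmr", "3.1.1", "rural", c(2010, 2016), c(30.1, 20.0))),
    rbind(row("u5mr", "3.2.1", "total", c(2010, 2016), c(16.4, 10.2)),
          row("u5mr", "3.2.1", "urban", c(2010, 2016), c(7.3, 5.2)),
          row("u5mr", "3.2.1", "rural", c(2010, 2016), c(20.1, 12.4))),
    rbind(row("nmr", "3.2.2", "total", c(2010, 2016), c(8.3, 4.9)),
          row("nmr", "3.2.2", "urban", c(2010, 2016), c(4.1, 3.0)),
          row("nmr", "3.2.2", "rural", c(2010, 2016), c(10.0, 5.7))),
    strat6("suicide", "3.4.2", c(2013, 2016),
           totals = c(7.69, 7.05), male = c(8.7, 8.1), female = c(6.7, 6.0),
           urban = c(5.3, 4.9), rural = c(8.8, 8.1)),
    rbind(row("road_injury", "3.6.1", "urban_total", c(2010, 2015),
              c(8.7, 13.2)),
          row("road_injury", "3.6.1", "urban_male", c(2010, 2015),
              c(12.2, 18.8)),
          row("road_injury", "3.6.1", "urban_female", c(2010, 2015),
              c(5.0, 7.4)),
          row("road_injury", "3.6.1", "rural_total", c(2010, 2015),
              c(15.3, 19.3)),
          row("road_injury", "3.6.1", "rural_male", c(2010, 2015),
              c(22.9, 28.6)),
          row("road_injury", "3.6.1", "rural_female", c(2010, 2015),
              c(7.4, 9.6))))
  rownames(out) <- NULL
  out
}

#' Look up one fixture value
#'
#' Convenience accessor over [fixture_disparities()].
#'
#' @param measure measure name or registry indicator id.
#' @param stratum stratum label.
#' @param year calendar year.
#' @return The value, or an error if the combination is absent.
#' @export
#' @examples
#' fixture_value("2.2.1", "male", 2013)  # 8.7
fixture_value <- function(measure, stratum, year) {
  d <- fixture_disparities()
  hit <- (d$measure == measure | d$indicator_id == measure) &
    d$stratum == stratum & d$year == year
  if (sum(hit) != 1) {
    stop("no unique fixture value for (", measure, ", ", stratum, ", ",
         year, ")", call. = FALSE)
  }
  d$value[hit]
}
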