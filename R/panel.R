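#' Read a long-format indicator panel from CSV
#'
#' A panel holds observed or estimated indicator values by location,
#' indicator, sex and year, one record per combination. Records are validated
#' against the registry: every indicator must be registered, values must lie
#' in the indicator's transform domain (non-negative for log-scaled rates,
#' within \[0, 1\] for logit-scaled proportions), years within 1990-2030, and
#' (location, indicator, sex, year) keys must be unique.
#'
#' @param path path to a CSV with header
#'   `location_id, region, indicator_id, sex, year, value`.
#' @param registry registry data frame, default [sdg_registry()].
#' @return A validated panel data frame.
#' @export
read_panel <- function(path, registry = sdg_registry()) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  panel <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(indicator_id = "character",
                                          location_id = "character"))
  validate_panel(panel, registry)
}

#' Validate an indicator panel against a registry
#'
#' @inheritParams read_panel
#' @param panel a panel data frame.
#' @return The panel, invisibly validated (year coerced to integer).
#' @export
validate_panel <- function(panel, registry = sdg_registry()) {
  required <- c("location_id", "region", "indicator_id", "sex", "year",
                "value")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols)) {
    stop("panel schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  panel$year <- as.integer(panel$year)
  panel$value <- as.numeric(panel$value)

  bad_region <- setdiff(unique(panel$region), .valid_regions)
  if (length(bad_region)) {
    stop("panel schema error: unknown region(s) ",
         paste(bad_region, collapse = ", "), call. = FALSE)
  }
  bad_sex <- setdiff(unique(panel$sex), .valid_sexes)
  if (length(bad_sex)) {
    stop("panel schema error: unknown sex value(s) ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  if (any(panel$year < 1990L | panel$year > 2030L)) {
    stop("panel schema error: years must lie within 1990-2030", call. = FALSE)
  }

  key <- paste(panel$location_id, panel$indicator_id, panel$sex, panel$year,
               sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate panel key(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "),
         call. = FALSE)
  }

  unknown <- setdiff(unique(panel$indicator_id), registry$indicator_id)
  if (length(unknown)) {
    stop("panel references indicator(s) not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  # domain checks per indicator transform (log allows exact zeros here; the
  # scaling step substitutes the series-specific floor)
  for (id in unique(panel$indicator_id)) {
    tr <- registry_row(registry, id)$transform
    v <- panel$value[panel$indicator_id == id]
    ok <- in_transform_domain(v, tr, strict = FALSE)
    if (!all(ok)) {
      bad <- which(panel$indicator_id == id)[which(!ok)[1]]
      stop("value out of ", tr, " domain for indicator ", id, " at key (",
           panel$location_id[bad], ", ", id, ", ", panel$sex[bad], ", ",
           panel$year[bad], "): ", panel$value[bad], call. = FALSE)
    }
  }
  panel
}

#' Write a panel to CSV
#'
#' Writes with a deterministic column order and row order (location,
#' indicator, sex, year) so identical panels produce byte-identical files.
#'
#' @param panel a panel data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  cols <- c("location_id", "region", "indicator_id", "sex", "year", "value")
  panel <- panel[do.call(order, panel[c("location_id", "indicator_id", "sex",
                                        "year")]), cols]
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write pipeline outputs to a report directory
#'
#' Writes whichever of the score, topic-index and projection tables are
#' supplied as CSV files (`scores.csv`, `topics.csv`, `projections.csv`)
#' under `path`, with deterministic column and row order. When several
#' tables are supplied their location keys are cross-checked.
#'
#' @param scores attainment score table from [scale_panel()], or `NULL`.
#' @param topic_indices topic index table from [aggregate_topics()], or
#'   `NULL`.
#' @param projections projection table from [project_panel()], or `NULL`.
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(scores = NULL, topic_indices = NULL,
                         projections = NULL, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)

  locs <- list(scores = scores$location_id,
               topics = topic_indices$location_id,
               projections = projections$location_id)
  locs <- lapply(Filter(Negate(is.null), locs), unique)
  if (length(locs) > 1) {
    base <- locs[[1]]
    for (k in seq_along(locs)[-1]) {
      extra <- setdiff(locs[[k]], base)
      if (length(extra)) {
        stop("inconsistent report inputs: ", names(locs)[k],
             " has location(s) absent from ", names(locs)[1], ": ",
             paste(extra, collapse = ", "), call. = FALSE)
      }
    }
  }

  write_one <- function(df, keys, cols, file) {
    df <- df[do.call(order, df[keys]), cols, drop = FALSE]
    utils::write.csv(df, file.path(path, file), row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(scores)) {
    write_one(scores,
              c("location_id", "indicator_id", "sex", "year"),
              c("location_id", "region", "indicator_id", "sex", "year",
                "value", "score", "worst", "target"),
              "scores.csv")
  }
  if (!is.null(topic_indices)) {
    write_one(topic_indices,
              c("location_id", "topic", "sex", "year"),
              c("location_id", "topic", "sex", "year", "index", "n_members",
                "members"),
              "topics.csv")
  }
  if (!is.null(projections)) {
    write_one(projections,
              c("location_id", "indicator_id", "sex", "year"),
              c("location_id", "region", "indicator_id", "sex", "year",
                "value", "omega"),
              "projections.csv")
  }
  invisible(path)
}

#' Read back a report directory written by [write_report()]
#'
#' @param path report directory.
#' @return A list with elements `scores`, `topic_indices`, `projections`
#'   (those present in the directory; `NULL` otherwise).
#' @export
read_report <- function(path) {
  read_one <- function(file) {
    f <- file.path(path, file)
    if (!file.exists(f)) return(NULL)
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    if ("indicator_id" %in% names(df)) {
      df$indicator_id <- as.character(df$indicator_id)
    }
    if ("location_id" %in% names(df)) {
      df$location_id <- as.character(df$location_id)
    }
    df
  }
  list(scores = read_one("scores.csv"),
       topic_indices = read_one("topics.csv"),
       projections = read_one("projections.csv"))
}
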