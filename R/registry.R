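#' The packaged 28-indicator SDG registry
#'
#' Returns the registry of the 28 health-related SDG monitoring indicators
#' tracked by the package: identity, thematic topic, direction of benefit,
#' scaling transform, target specification and target year. Targets follow
#' the SDG resolutions and WHO guideline documents; where a target has no
#' published numeric value the packaged convention is flagged in the
#' `assumption` column.
#'
#' @return A data frame with one row per indicator and columns
#'   `indicator_id`, `name`, `topic`, `direction`, `transform`,
#'   `target_type`, `target_value`, `baseline_year`, `target_year`, `units`,
#'   `assumption`.
#' @seealso [load_registry()] to read a registry from a CSV file of the same
#'   layout.
#' @export
#' @examples
#' reg <- sdg_registry()
#' table(reg$topic)
sdg_registry <- function() {
  path <- system.file("extdata", "registry.csv", package = "sdgtrack",
                      mustWork = TRUE)
  load_registry(path)
}

#' Read an indicator registry from CSV
#'
#' Reads and validates a registry file (UTF-8, comma-separated, `.` decimal).
#' Validation enforces the expected cardinality, known enum levels for topic,
#' direction, transform and target type, unique indicator ids, target years
#' in {2020, 2025, 2030}, non-empty topics, and `0 < target_value < 1` for
#' relative-reduction targets.
#'
#' @param path path to a registry CSV.
#' @param n_expected expected number of indicator rows (default 28, the full
#'   registry). Use `NULL` to accept any non-zero cardinality, e.g. for
#'   reduced test registries.
#' @return A validated registry data frame (see [sdg_registry()]).
#' @export
load_registry <- function(path, n_expected = 28L) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(indicator_id = "character"))
  required <- c("indicator_id", "name", "topic", "direction", "transform",
                "target_type", "target_value", "baseline_year", "target_year",
                "units")
  missing_cols <- setdiff(required, names(reg))
  if (length(missing_cols)) {
    stop("registry schema error: missing field(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"assumption" %in% names(reg)) reg$assumption <- FALSE
  validate_registry(reg, n_expected = n_expected)
  reg
}

validate_registry <- function(reg, n_expected = 28L) {
  if (!is.null(n_expected) && nrow(reg) != n_expected) {
    stop("registry schema error: expected ", n_expected,
         " indicator rows, found ", nrow(reg), call. = FALSE)
  }
  dup <- reg$indicator_id[duplicated(reg$indicator_id)]
  if (length(dup)) {
    stop("duplicate indicator_id in registry: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(reg))) {
    row <- reg[i, ]
    bad_field <- function(field, allowed) {
      if (!row[[field]] %in% allowed) {
        stop("registry schema error in row ", i, " (", row$indicator_id,
             "): invalid ", field, " '", row[[field]], "'", call. = FALSE)
      }
    }
    bad_field("topic", .valid_topics)
    bad_field("direction", .valid_directions)
    bad_field("transform", .valid_transforms)
    bad_field("target_type", .valid_target_type)
    if (!row$target_year %in% c(2020L, 2025L, 2030L)) {
      stop("registry schema error in row ", i, " (", row$indicator_id,
           "): target_year must be 2020, 2025 or 2030", call. = FALSE)
    }
    if (row$target_type == "relative_reduction" &&
        (is.na(row$target_value) || row$target_value <= 0 ||
         row$target_value >= 1)) {
      stop("registry schema error in row ", i, " (", row$indicator_id,
           "): relative_reduction needs 0 < target_value < 1", call. = FALSE)
    }
    if (row$target_type == "absolute" && is.na(row$target_value)) {
      stop("registry schema error in row ", i, " (", row$indicator_id,
           "): absolute target needs a target_value", call. = FALSE)
    }
    if (row$target_type %in% c("relative_reduction", "no_increase") &&
        is.na(row$baseline_year)) {
      stop("registry schema error in row ", i, " (", row$indicator_id,
           "): ", row$target_type, " target needs a baseline_year",
           call. = FALSE)
    }
  }
  if (is.null(n_expected) || n_expected == 28L) {
    empty <- setdiff(.valid_topics, unique(reg$topic))
    if (length(empty)) {
      stop("registry schema error: empty topic(s): ",
           paste(empty, collapse = ", "), call. = FALSE)
    }
  }
  invisible(reg)
}

#' Topic membership of the registry
#'
#' @param registry a registry data frame, default the packaged one.
#' @return A named list mapping each thematic topic to the character vector
#'   of member indicator ids, in registry order.
#' @export
#' @examples
#' lengths(topic_members())
topic_members <- function(registry = sdg_registry()) {
  split(registry$indicator_id, factor(registry$topic, levels = .valid_topics))
}

# Single-row registry lookup; errors on unknown id.
registry_row <- function(registry, indicator_id) {
  k <- match(indicator_id, registry$indicator_id)
  if (is.na(k)) {
    stop("indicator '", indicator_id, "' not present in registry",
         call. = FALSE)
  }
  registry[k, ]
}
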