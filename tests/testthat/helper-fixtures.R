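# shared builders for small in-memory fixtures

# one-indicator, one-location panel from a value series
series_panel <- function(values, years = seq(1990, length.out = length(values)),
                         indicator_id = "3.2.1", location_id = "P01",
                         region = "eastern", sex = "both") {
  data.frame(location_id = location_id, region = region,
             indicator_id = indicator_id, sex = sex,
             year = years, value = values, stringsAsFactors = FALSE)
}

# a registry row as a one-row data frame, defaulting to a log-scaled
# mortality-style indicator with an absolute target
fake_definition <- function(indicator_id = "x", direction = "lower_better",
                            transform = "log", target_type = "absolute",
                            target_value = 2, baseline_year = NA_integer_,
                            target_year = 2030L, topic = "mchrh") {
  data.frame(indicator_id = indicator_id, name = "test indicator",
             topic = topic, direction = direction, transform = transform,
             target_type = target_type, target_value = target_value,
             baseline_year = baseline_year, target_year = target_year,
             units = "units", assumption = FALSE, stringsAsFactors = FALSE)
}

# geometric-decay series x0 * exp(rate * t)
decay_series <- function(x0, rate, n = 27, t0 = 0) {
  x0 * exp(rate * (seq_len(n) - 1 + t0))
}

cli_script <- function() {
  system.file("exec", "sdgtrack.R", package = "sdgtrack")
}

run_cli <- function(args) {
  out <- suppressWarnings(
    system2("Rscript", c(cli_script(), args), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
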