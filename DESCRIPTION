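Package: sdgtrack
Title: Attainment Indices and Trend Projections for Health-Related SDG
    Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for tracking progress toward the health-related
    Sustainable Development Goal (SDG) targets from long-format indicator
    panels. Raw indicator values are rescaled to a 0-100 attainment index
    anchored at the outlier-trimmed worst historical value (index 0) and the
    resolved SDG/WHO target (index 100), in log space for incidence and
    mortality rates. Indicator scores are combined into thematic-topic
    indices by equal-weight geometric means with a floor at 1, and projected
    to target years with a recency-weighted mean annual rate of change fitted
    per series. Includes achievement counting against a 90-point threshold,
    sex/rural-urban/regional disparity ratios, a synthetic panel generator
    for end-to-end testing, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
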