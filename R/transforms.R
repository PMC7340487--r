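#' Transform helpers for indicator scales
#'
#' Rate-type indicators (incidence, mortality) are handled in log space,
#' proportion-type indicators in logit space, and unbounded quantities on the
#' identity scale. All scaling and projection arithmetic in the package goes
#' through these two functions so that the transform conventions live in one
#' place.
#'
#' @param x numeric vector in indicator units (for `apply_transform`) or in
#'   transform space (for `inv_transform`).
#' @param transform one of `"log"`, `"logit"`, `"linear"`.
#' @return numeric vector of the same length.
#' @keywords internal
apply_transform <- function(x, transform) {
  switch(transform,
    log    = log(x),
    logit  = log(x / (1 - x)),
    linear = x,
    stop("unknown transform: ", transform, call. = FALSE)
  )
}

#' @rdname apply_transform
#' @keywords internal
inv_transform <- function(x, transform) {
  switch(transform,
    log    = exp(x),
    logit  = 1 / (1 + exp(-x)),
    linear = x,
    stop("unknown transform: ", transform, call. = FALSE)
  )
}

# TRUE where a value lies strictly inside the transform's open domain
# (log: x > 0; logit: 0 < x < 1). Zeros under log are handled separately by
# the anchor-resolution floor, not here.
in_transform_domain <- function(x, transform, strict = TRUE) {
  switch(transform,
    log    = if (strict) x > 0 else x >= 0,
    logit  = if (strict) x > 0 & x < 1 else x >= 0 & x <= 1,
    linear = is.finite(x),
    stop("unknown transform: ", transform, call. = FALSE)
  )
}

.valid_transforms  <- c("log", "logit", "linear")
.valid_directions  <- c("lower_better", "higher_better")
.valid_target_type <- c("absolute", "relative_reduction", "no_increase",
                        "elimination")
.valid_topics <- c("child_nutrition", "mchrh", "infectious", "ncd_mortality",
                   "ncd_risk", "road_injury", "env_outcome", "env_exposure",
                   "uhc")
.valid_regions <- c("eastern", "central", "western", "national", "SAR")
.valid_sexes   <- c("male", "female", "both")
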