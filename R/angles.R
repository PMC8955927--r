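#' Transformed performance
#'
#' Converts a signed report error angle into the bounded transformed
#' performance measure `TP = 1 - |error| / 180`. `TP = 1` corresponds to a
#' perfect report and `TP = 0.5` to chance-level average performance (the
#' expectation under uniform guessing over the full error range).
#'
#' @param error_deg Numeric vector of signed error angles in degrees, each in
#'   `[-180, 180]`.
#' @return Numeric vector of the same length with values in `[0, 1]`.
#' @examples
#' transform_performance(c(0, -90, 180))
#' @export
transform_performance <- function(error_deg) {
  if (!is.numeric(error_deg) || anyNA(error_deg) || any(!is.finite(error_deg))) {
    abort("`error_deg` must be finite numeric.", class = "memmixr_domain_error")
  }
  if (any(error_deg < -180 | error_deg > 180)) {
    abort("`error_deg` must lie in [-180, 180].", class = "memmixr_domain_error")
  }
  1 - abs(error_deg) / 180
}

#' Wrap an angle onto the signed error domain
#'
#' Reduces any finite angle modulo 360 onto the half-open interval
#' `(-180, 180]`; in particular `-180` maps to `180`, so the maximal deviation
#' has a unique representation.
#'
#' @param angle_deg Numeric vector of angles in degrees.
#' @return Numeric vector of equivalent angles in `(-180, 180]`.
#' @examples
#' wrap_error(c(190, -180, 45, 720))
#' @export
wrap_error <- function(angle_deg) {
  if (!is.numeric(angle_deg) || anyNA(angle_deg) || any(!is.finite(angle_deg))) {
    abort("`angle_deg` must be finite numeric.", class = "memmixr_domain_error")
  }
  180 - ((180 - angle_deg) %% 360)
}
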