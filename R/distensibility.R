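#' Aortic diameter distensibility
#'
#' Relative systolic-diastolic expansion of the ascending aorta at the
#' sinotubular junction: `(dmax - dmin)/dmin`, where `dmax` is the inner
#' diameter in the frame before aortic-valve closure (end-systole) and `dmin`
#' in the frame before valve opening (end-diastole).  The value is returned
#' as a dimensionless fraction; use [dd_percent()] for display as a
#' percentage.  Distensibility is a blood-pressure-free surrogate for
#' arterial elasticity, which makes it usable in fetuses where pressure
#' cannot be measured non-invasively.
#'
#' @param dmax End-systolic diameter, mm. Must satisfy `dmax >= dmin`.
#' @param dmin End-diastolic diameter, mm. Must be positive.
#' @return Dimensionless fraction, `>= 0`. Vectorised.
#' @examples
#' distensibility(4.62, 4.2)  # 0.10
#' dd_percent(distensibility(4.62, 4.2))  # 10
#' @export
distensibility <- function(dmax, dmin) {
  dmax <- as.numeric(dmax)
  dmin <- as.numeric(dmin)
  if (length(dmax) != length(dmin)) {
    stop_typed("invalid_measurement", "dmax and dmin must have equal length")
  }
  if (any(!is.finite(dmin)) || any(dmin <= 0)) {
    stop_typed("invalid_measurement",
               "dmin must be positive: a non-positive diastolic diameter is not a measurement")
  }
  if (any(dmax < dmin)) {
    stop_typed("inconsistent_frames",
               "dmax < dmin: the end-systolic diameter must not be smaller than the end-diastolic one")
  }
  (dmax - dmin) / dmin
}

#' Render a distensibility fraction as percent
#'
#' Presentation helper only; distensibility is stored and modelled as a
#' fraction throughout the package.
#'
#' @param dd Dimensionless distensibility fraction(s).
#' @return `dd * 100`.
#' @export
dd_percent <- function(dd) 100 * as.numeric(dd)
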