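#' Fit a film dose-response (H-D) calibration curve
#'
#' Fits a monotone shape-preserving Hermite spline (Fritsch-Carlson
#' slopes) mapping net optical density back to dose. The fit
#' interpolates the knots exactly, is monotone everywhere, and is used
#' only within the measured response range.
#'
#' @param doses graded doses, cGy, strictly increasing, >= 3 points.
#' @param responses net optical densities, strictly increasing, same
#'   length.
#' @return object of class `"hd_curve"`.
#' @export
#' @examples
#' cal <- fit_calibration(c(5, 100, 200), c(0.1, 0.8, 1.2))
#' apply_calibration(cal, 0.8)  # 100, a knot
fit_calibration <- function(doses, responses) {
  if (!is.numeric(doses) || !is.numeric(responses) ||
      length(doses) != length(responses) || length(doses) < 3L) {
    stop("need >= 3 paired (dose, response) points", call. = FALSE)
  }
  if (any(diff(doses) <= 0) || any(diff(responses) <= 0)) {
    stop("doses and responses must both be strictly increasing", call. = FALSE)
  }
  structure(
    list(doses = doses, responses = responses,
         fun = stats::splinefun(responses, doses, method = "monoH.FC")),
    class = "hd_curve")
}

#' Convert a film response to dose via a fitted H-D curve
#'
#' @param curve an [`fit_calibration()`] result.
#' @param response net optical density value(s) within the calibrated
#'   range; extrapolation errors.
#' @return dose(s) in cGy.
#' @export
apply_calibration <- function(curve, response) {
  stopifnot(inherits(curve, "hd_curve"))
  rng <- range(curve$responses)
  if (any(response < rng[1]) || any(response > rng[2])) {
    stop(sprintf("response outside calibrated range [%.4g, %.4g]",
                 rng[1], rng[2]), call. = FALSE)
  }
  curve$fun(response)
}

#' @export
print.hd_curve <- function(x, ...) {
  cat(sprintf("H-D calibration curve: %d knots, dose %.4g-%.4g cGy, net OD %.4g-%.4g\n",
              length(x$doses), min(x$doses), max(x$doses),
              min(x$responses), max(x$responses)))
  invisible(x)
}
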