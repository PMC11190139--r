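#' Fit a 3rd-order polynomial to a depth profile
#'
#' Ordinary least squares of the profile values on a cubic in normalized
#' depth. Missing depth bins are excluded from the fit, never imputed; at
#' least `minPoints` of the bins must be present.
#'
#' @param profile a [DepthProfile-class].
#' @param minPoints minimum non-missing points required (default 8 of 10).
#' @return numeric(4) cubic coefficients, constant term first.
#' @export
fitProfilePolynomial <- function(profile, minPoints = 8L) {
  x <- profileDepths(profile)
  y <- profileValues(profile)
  ok <- !is.na(y)
  if (sum(ok) < minPoints)
    stop(sprintf("insufficient data: %d non-missing points, need >= %d",
                 sum(ok), minPoints))
  X <- cbind(1, x[ok], x[ok]^2, x[ok]^3)
  co <- stats::lm.fit(X, y[ok])$coefficients
  unname(co)
}

#' Global mean of a depth profile
#'
#' Arithmetic mean of the non-missing depth values — the depth-blind
#' ROI-level summary.
#'
#' @inheritParams fitProfilePolynomial
#' @return the mean value (ms).
#' @export
profileMean <- function(profile, minPoints = 8L) {
  y <- profileValues(profile)
  if (sum(!is.na(y)) < minPoints)
    stop(sprintf("insufficient data: %d non-missing points, need >= %d",
                 sum(!is.na(y)), minPoints))
  mean(y, na.rm = TRUE)
}

#' Area under the fitted profile polynomial
#'
#' Closed-form integral of the fitted cubic over the ribbon, in depth-index
#' units: `auc = 10 * integral_0^1 p(x) dx`, so a flat profile of value `c`
#' has AUC `10 * c`. The factor 10 makes the AUC commensurate with a sum
#' over the 10 depth samples.
#'
#' @param coeffs cubic coefficients from [fitProfilePolynomial()].
#' @return the AUC (ms * depth-index).
#' @export
profileAuc <- function(coeffs) {
  stopifnot(length(coeffs) == 4L)
  10 * (coeffs[1] + coeffs[2] / 2 + coeffs[3] / 3 + coeffs[4] / 4)
}

#' Profile offset at the WM/GM transitional zone
#'
#' The fitted polynomial evaluated at depth 0, i.e. the quantitative value
#' at the WM/GM boundary.
#'
#' @param coeffs cubic coefficients from [fitProfilePolynomial()].
#' @return the offset (ms).
#' @export
profileOffset <- function(coeffs) {
  stopifnot(length(coeffs) == 4L)
  coeffs[1]
}

#' All three scalar metrics of a depth profile
#'
#' Convenience wrapper computing the global mean, polynomial AUC and WM/GM
#' offset of one profile.
#'
#' @inheritParams fitProfilePolynomial
#' @return a [ProfileMetrics-class] object.
#' @examples
#' p <- new("DepthProfile", subjectId = "s", roi = "lOFC",
#'          hemisphere = "averaged", contrast = "T1",
#'          depths = (1:10 - 0.5) / 10,
#'          values = baselineProfile((1:10 - 0.5) / 10),
#'          nVoxels = rep(100L, 10))
#' profileMetrics(p)
#' @export
profileMetrics <- function(profile, minPoints = 8L) {
  co <- fitProfilePolynomial(profile, minPoints)
  new("ProfileMetrics",
      meanValue = profileMean(profile, minPoints),
      auc = profileAuc(co), offset = profileOffset(co), coeffs = co)
}
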