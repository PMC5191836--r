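# Rhythm parameters derived from fitted harmonic coefficients.
#
# A fitted harmonic alpha*cos(wt) + beta*sin(wt) equals
# sqrt(alpha^2 + beta^2) * cos(wt - atan2(beta, alpha)), so its
# peak-trough swing is 2*sqrt(alpha^2 + beta^2) and its maximum occurs at
# t = atan2(beta, alpha) / w.

#' Peak-trough amplitude of a fitted harmonic
#'
#' `2 * sqrt(alpha^2 + beta^2)`: the difference between the fitted curve's
#' maximum and minimum, in the units of the signal (log2 for expression
#' data).
#'
#' @param alpha,beta cosine and sine coefficients (vectorized).
#' @return Peak-trough amplitude(s), `>= 0`.
#' @examples
#' amplitude(3, 4) # 10
#' @export
amplitude <- function(alpha, beta) 2 * sqrt(alpha^2 + beta^2)

#' Peak phase of a fitted harmonic, in hours
#'
#' The time of the fitted curve's maximum: `atan2(beta, alpha) * period /
#' (2*pi)`, mapped into `[0, period)`. For a zero harmonic (`alpha = beta
#' = 0`) the phase is undefined and `NA` is returned.
#'
#' @param alpha,beta cosine and sine coefficients (vectorized).
#' @param period oscillation period in hours.
#' @return Peak time(s) in `[0, period)` hours, `NA` where undefined.
#' @examples
#' phase_hours(0, 1) # 6
#' @export
phase_hours <- function(alpha, beta, period = 24) {
  ph <- (atan2(beta, alpha) * period / (2 * pi)) %% period
  ph[alpha == 0 & beta == 0] <- NA_real_
  ph
}

#' Relative amplitude of an expression profile
#'
#' The difference of maximum and minimum expression levels normalized by
#' the mean over all time points, computed on the per-time-point means of
#' one condition. Dimensionless and invariant to positive scaling of the
#' profile.
#'
#' @param profile numeric vector of per-time-point mean levels.
#' @return `(max - min) / mean`, or `NA` when the mean is zero.
#' @examples
#' relative_amplitude(c(2, 4, 6, 8)) # 1.2
#' @export
relative_amplitude <- function(profile) {
  stopifnot(is.numeric(profile), length(profile) >= 1L)
  if (anyNA(profile)) return(NA_real_)
  m <- mean(profile)
  if (m == 0) return(NA_real_)
  (max(profile) - min(profile)) / m
}

#' Circular distance between two phases
#'
#' The shortest distance around the clock between two peak times, in
#' `[0, period/2]` hours. Undefined (`NA`) phases propagate.
#'
#' @param p1,p2 phases in hours (vectorized).
#' @param period period in hours.
#' @return Distance(s) in hours.
#' @examples
#' circular_phase_distance(22.2, 17.5) # 4.7
#' circular_phase_distance(1, 23)      # 2
#' @export
circular_phase_distance <- function(p1, p2, period = 24) {
  d <- abs(p1 - p2) %% period
  pmin(d, period - d)
}
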