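# Uncertainty bookkeeping: generalization-bias characterization, quadrature
# combination of independent fractional error sources, and confidence
# intervals around central death estimates.

#' Mean absolute bias of a set of relative errors
#'
#' Used to characterize the bias the generalization introduces at the large
#' scale: the mean of the absolute values of the evaluation relative errors.
#'
#' @param relative_errors Non-empty numeric vector of fractional errors
#'   (e.g. -0.07 for a 7 percent underestimate).
#' @return Mean absolute value, a fraction.
#' @export
mean_absolute_bias <- function(relative_errors) {
  if (length(relative_errors) == 0L) {
    stop("input error: empty list of relative errors", call. = FALSE)
  }
  mean(abs(relative_errors))
}

#' Combine independent fractional uncertainties in quadrature
#'
#' @param components Nonnegative fractional uncertainties assumed
#'   independent.
#' @return Square root of the sum of squares, a fraction.
#' @export
combine_quadrature <- function(components) {
  if (any(components < 0)) {
    stop("input error: components must be nonnegative", call. = FALSE)
  }
  sqrt(sum(components^2))
}

#' Report a combined fractional uncertainty as a whole percent
#'
#' @param fraction A fraction as from [combine_quadrature()].
#' @return Integer percent.
#' @export
percent_rounded <- function(fraction) {
  round(100 * fraction)
}

#' Confidence interval around a central death estimate
#'
#' Symmetric multiplicative interval `central * (1 -/+ combined)`, with each
#' bound rounded to the nearest `rounding` deaths (default nearest 1,000,
#' the granularity used for national projections).
#'
#' @param central Central estimate, deaths/year (> 0).
#' @param combined Combined fractional uncertainty in [0, 1).
#' @param rounding Rounding granularity in deaths.
#' @return Named numeric `c(low, high)`.
#' @export
confidence_interval <- function(central, combined, rounding = 1000) {
  if (!is.finite(central) || central <= 0) {
    stop("input error: `central` must be > 0", call. = FALSE)
  }
  if (combined < 0 || combined >= 1) {
    stop("input error: `combined` must be in [0, 1)", call. = FALSE)
  }
  c(low = round(central * (1 - combined) / rounding) * rounding,
    high = round(central * (1 + combined) / rounding) * rounding)
}
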