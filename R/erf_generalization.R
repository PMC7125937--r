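# Exposure-response generalization: per-city quadratic fits, regression of
# the fitted coefficients on summer mean temperature (SMT), and the resulting
# generalized relative-risk function with its clamping rules.
#
# The model: with T the daily mean temperature in degC above the local
# optimal temperature (OT), each city's curve is RR = 1 + a*T^2 + b*T, and
# the fitted (a, b) vary approximately linearly with the city's SMT. The
# generalized function evaluates
#   RR = 1 + slope_a*(SMT - xint_a)*T^2 + slope_b*(SMT - xint_b)*T
# for T > 0, with RR = 1 at and below OT and a lower clamp of 1 elsewhere.

#' Summer mean temperatures for the ten reference U.S. cities
#'
#' June--August mean temperatures (degC) for the ten cities whose observed
#' exposure-response curves anchor the generalization: Atlanta, Boston,
#' Chicago, Dallas, Houston, Los Angeles, Miami, New York, Philadelphia,
#' and Washington D.C.
#'
#' @return Named numeric vector of ten SMTs, degC.
#' @export
us_city_smt <- function() {
  c(atlanta = 25.7, boston = 21.2, chicago = 22.5, dallas = 28.9,
    houston = 28.4, los_angeles = 21.8, miami = 28.4, new_york = 23.1,
    philadelphia = 23.9, washington_dc = 24.4)
}

#' One city's observed exposure-response curve
#'
#' Relative risk sampled at 0.1 degC increments of daily mean temperature,
#' with the city's optimal temperature (OT, where RR is defined to be 1) and
#' summer mean temperature (SMT).
#'
#' @param city_id Label.
#' @param smt Summer mean temperature, degC.
#' @param ot Optimal (minimum-mortality) temperature, degC.
#' @param temp Strictly increasing sample temperatures, degC, at 0.1
#'   increments.
#' @param rr Nonnegative relative risks at `temp`.
#' @return An object of class `erf_curve` (a data frame with columns
#'   `temp`, `rr` and attributes `city_id`, `smt`, `ot`).
#' @export
erf_curve <- function(city_id, smt, ot, temp, rr) {
  stopifnot(length(temp) == length(rr))
  if (any(diff(temp) <= 0)) {
    stop("input error: `temp` must be strictly increasing", call. = FALSE)
  }
  if (max(abs(diff(temp) - 0.1)) > 1e-6) {
    stop("input error: `temp` must be sampled at 0.1 degC increments",
         call. = FALSE)
  }
  if (any(rr < 0)) {
    stop("input error: `rr` must be nonnegative", call. = FALSE)
  }
  structure(data.frame(temp = temp, rr = rr),
            city_id = city_id, smt = smt, ot = ot,
            class = c("erf_curve", "data.frame"))
}

#' Fit a second-order polynomial to one city's curve
#'
#' Least-squares fit of RR on T = temp - OT, restricted to the hot side
#' (T >= 0). Variant A fits `rr = c + b*T + a*T^2` with a free constant and
#' reports the offset `c - 1` as a diagnostic; variant B forces the curve
#' through RR = 1 at T = 0 by fitting `rr - 1 = b*T + a*T^2` with no
#' constant.
#'
#' @param curve An [erf_curve()].
#' @param variant `"A"` (free offset, the primary parameterization) or
#'   `"B"` (forced through one).
#' @return A list of class `poly_coef`: `a`, `b`, `offset`, `variant`,
#'   `smt`, `city_id`.
#' @export
fit_city_polynomial <- function(curve, variant = c("A", "B")) {
  variant <- match.arg(variant)
  stopifnot(inherits(curve, "erf_curve"))
  tt <- curve$temp - attr(curve, "ot")
  keep <- tt >= 0
  tt <- tt[keep]
  rr <- curve$rr[keep]
  if (length(tt) < 3L) {
    stop("degenerate input: fewer than 3 samples at or above OT", call. = FALSE)
  }
  if (diff(range(tt)) < 1e-12) {
    stop("degenerate input: all usable temperatures are equal", call. = FALSE)
  }
  if (variant == "A") {
    fit <- stats::lm(rr ~ tt + I(tt^2))
    cf <- stats::coef(fit)
    out <- list(a = unname(cf[3]), b = unname(cf[2]),
                offset = unname(cf[1]) - 1)
  } else {
    y <- rr - 1
    fit <- stats::lm(y ~ 0 + tt + I(tt^2))
    cf <- stats::coef(fit)
    out <- list(a = unname(cf[2]), b = unname(cf[1]), offset = 0)
  }
  if (!all(is.finite(c(out$a, out$b)))) {
    stop("degenerate input: non-finite fitted coefficients", call. = FALSE)
  }
  out$variant <- variant
  out$smt <- attr(curve, "smt")
  out$city_id <- attr(curve, "city_id")
  class(out) <- "poly_coef"
  out
}

#' Regress fitted curve coefficients on summer mean temperature
#'
#' Ordinary least squares of the per-city quadratic coefficient `a` and
#' linear coefficient `b` on city SMT. Slopes are taken directly from the
#' fits; x-intercepts are `-intercept/slope`. The two Pearson correlations of
#' the fits are returned for diagnostics.
#'
#' @param coefs List of [fit_city_polynomial()] results (each carrying its
#'   city's `smt`), or a data frame with columns `smt`, `a`, `b`.
#' @return A list of class `gen_erf_params`: `slope_a`, `xint_a`, `slope_b`,
#'   `xint_b`, `r_a`, `r_b`, `variant`.
#' @export
regress_coefficients <- function(coefs) {
  df <- if (is.data.frame(coefs)) {
    coefs
  } else {
    data.frame(smt = vapply(coefs, `[[`, numeric(1), "smt"),
               a = vapply(coefs, `[[`, numeric(1), "a"),
               b = vapply(coefs, `[[`, numeric(1), "b"))
  }
  if (nrow(df) < 3L || length(unique(df$smt)) < 3L) {
    stop("input error: need >= 3 points with distinct SMT", call. = FALSE)
  }
  variant <- if (!is.data.frame(coefs)) coefs[[1]]$variant else NA_character_
  fa <- stats::lm(a ~ smt, data = df)
  fb <- stats::lm(b ~ smt, data = df)
  ca <- stats::coef(fa)
  cb <- stats::coef(fb)
  if (abs(ca[2]) < 1e-15 || abs(cb[2]) < 1e-15) {
    stop("non-identifiable: a coefficient regression has zero slope, ",
         "x-intercept undefined", call. = FALSE)
  }
  structure(
    list(slope_a = unname(ca[2]), xint_a = unname(-ca[1] / ca[2]),
         slope_b = unname(cb[2]), xint_b = unname(-cb[1] / cb[2]),
         r_a = stats::cor(df$smt, df$a), r_b = stats::cor(df$smt, df$b),
         variant = variant),
    class = "gen_erf_params"
  )
}

#' Published generalized-function parameter presets
#'
#' `"eq2_variantA"` is the primary parameterization (free-offset city fits):
#' RR = 1 - 0.0014 (SMT - 30.9) T^2 + 0.005 (SMT - 26.7) T.
#' `"alt_variantB"` comes from city fits forced through RR = 1 at T = 0:
#' RR = 1 - 0.0011 (SMT - 32.3) T^2 + 0.0032 (SMT - 26.6) T.
#'
#' @param name Preset name.
#' @return A `gen_erf_params` object.
#' @export
erf_preset <- function(name = c("eq2_variantA", "alt_variantB")) {
  name <- match.arg(name)
  p <- switch(name,
    eq2_variantA = list(slope_a = -0.0014, xint_a = 30.9,
                        slope_b = 0.005, xint_b = 26.7,
                        r_a = NA_real_, r_b = NA_real_, variant = "A"),
    alt_variantB = list(slope_a = -0.0011, xint_a = 32.3,
                        slope_b = 0.0032, xint_b = 26.6,
                        r_a = NA_real_, r_b = NA_real_, variant = "B")
  )
  structure(p, class = "gen_erf_params")
}

#' Generalized relative risk at a daily temperature
#'
#' With T = `t_day - ot`: RR = 1 for T <= 0; otherwise
#' RR = max(1, 1 + slope_a (smt - xint_a) T^2 + slope_b (smt - xint_b) T).
#' The lower clamp removes the RR < 1 dip the raw quadratic produces at small
#' T when SMT is below `xint_b`. Cells with SMT above `xint_a` (where the
#' quadratic term turns negative and risk would eventually fall with
#' temperature) are evaluated as-is and counted in the `n_smt_above_xint`
#' attribute; such conditions are rare in the contiguous United States.
#'
#' Arguments are vectorized with the usual recycling.
#'
#' @param t_day Daily mean temperature, degC.
#' @param ot Optimal temperature, degC.
#' @param smt Summer mean temperature, degC.
#' @param params A `gen_erf_params`.
#' @param clamp If `FALSE`, return the raw (unclamped) value for T > 0;
#'   diagnostics only.
#' @return Numeric vector of relative risks, with attributes `n_clamped`
#'   (count of values lifted to 1 on the hot side) and `n_smt_above_xint`.
#' @export
relative_risk <- function(t_day, ot, smt, params, clamp = TRUE) {
  stopifnot(inherits(params, "gen_erf_params"))
  if (!all(is.finite(t_day)) || !all(is.finite(ot)) || !all(is.finite(smt))) {
    stop("input error: non-finite temperature inputs", call. = FALSE)
  }
  tt <- t_day - ot
  a <- params$slope_a * (smt - params$xint_a)
  b <- params$slope_b * (smt - params$xint_b)
  raw <- 1 + a * tt^2 + b * tt
  hot <- tt > 0
  rr <- ifelse(hot, if (clamp) pmax(1, raw) else raw, 1)
  attr(rr, "n_clamped") <- sum(hot & raw < 1)
  attr(rr, "n_smt_above_xint") <- sum(hot & (smt > params$xint_a))
  rr
}

#' Leave-one-city-out sensitivity of the coefficient regressions
#'
#' Re-runs [regress_coefficients()] n times, omitting one city each time, and
#' summarizes the spread of the leave-one-out slopes relative to the
#' all-cities slopes.
#'
#' @param coefs As in [regress_coefficients()]; at least 4 points.
#' @return List with `full` (all-points `gen_erf_params`), `loo` (data frame
#'   of per-left-out-city slopes), and for each slope the standard deviation
#'   and maximum absolute deviation of the LOO values relative to the
#'   all-points slope (`sd_rel_a`, `max_rel_a`, `sd_rel_b`, `max_rel_b`,
#'   as fractions).
#' @export
loo_sensitivity <- function(coefs) {
  df <- if (is.data.frame(coefs)) {
    coefs
  } else {
    data.frame(smt = vapply(coefs, `[[`, numeric(1), "smt"),
               a = vapply(coefs, `[[`, numeric(1), "a"),
               b = vapply(coefs, `[[`, numeric(1), "b"))
  }
  if (nrow(df) < 4L) {
    stop("input error: need >= 4 points for leave-one-out", call. = FALSE)
  }
  full <- regress_coefficients(df)
  loo <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    p <- regress_coefficients(df[-i, , drop = FALSE])
    data.frame(left_out = i, slope_a = p$slope_a, slope_b = p$slope_b)
  }))
  rel_a <- loo$slope_a / full$slope_a - 1
  rel_b <- loo$slope_b / full$slope_b - 1
  list(full = full, loo = loo,
       sd_rel_a = stats::sd(rel_a), max_rel_a = max(abs(rel_a)),
       sd_rel_b = stats::sd(rel_b), max_rel_b = max(abs(rel_b)))
}

#' Read / write exposure-response curves as CSV
#'
#' The interchange format has columns `city_id`, `temp_c`, `rr` plus
#' per-city `smt` and `ot` columns (constant within a city).
#'
#' @param curves List of [erf_curve()] objects.
#' @param path File path.
#' @return `write_erf_csv()` returns `path` invisibly; `read_erf_csv()` a
#'   named list of `erf_curve` objects.
#' @export
write_erf_csv <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(city_id = attr(cv, "city_id"), temp_c = cv$temp, rr = cv$rr,
               smt = attr(cv, "smt"), ot = attr(cv, "ot"))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_erf_csv
#' @export
read_erf_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- lapply(split(df, df$city_id), function(d) {
    erf_curve(city_id = d$city_id[1], smt = d$smt[1], ot = d$ot[1],
              temp = d$temp_c, rr = d$rr)
  })
  out[unique(df$city_id)]
}
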