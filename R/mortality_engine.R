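# Mortality engine: baseline rates, attributable deaths, scenario
# projection, and regional aggregation.
#
# Heat-attributable deaths for one cell-day are
#   population x daily baseline mortality rate x attributable fraction,
# with the attributable fraction taken as RR - 1 (the stated convention of
# the source method; the conventional (RR - 1)/RR form is available as a
# sensitivity switch).

#' Baseline all-cause mortality with monthly weighting
#'
#' @param annual_rate Deaths per person per year (> 0).
#' @param monthly_shares 12 positive fractions summing to 1 (see
#'   [gen_monthly_weights()]); each month's deaths are assumed uniform
#'   within the month.
#' @return An object of class `baseline_mortality`.
#' @export
baseline_mortality <- function(annual_rate, monthly_shares = gen_monthly_weights()) {
  if (!is.finite(annual_rate) || annual_rate <= 0) {
    stop("input error: `annual_rate` must be > 0", call. = FALSE)
  }
  if (length(monthly_shares) != 12L || any(monthly_shares <= 0) ||
      abs(sum(monthly_shares) - 1) > 1e-9) {
    stop("input error: `monthly_shares` must be 12 positive values summing to 1",
         call. = FALSE)
  }
  structure(list(annual_rate = annual_rate,
                 monthly_shares = as.numeric(monthly_shares)),
            class = "baseline_mortality")
}

#' Daily baseline mortality rate for given days of year
#'
#' rate = annual_rate * monthly_share[month] / days_in_month(month), so the
#' daily rates integrate back to the annual rate exactly over a 365-day year.
#'
#' @param bm A [baseline_mortality()].
#' @param doy Day-of-year (1..365); vectorized.
#' @return Deaths per person per day for each element of `doy`.
#' @export
daily_baseline_rate <- function(bm, doy = 1:365) {
  stopifnot(inherits(bm, "baseline_mortality"))
  if (any(doy < 1L) || any(doy > 365L)) {
    stop("input error: `doy` must be in 1..365", call. = FALSE)
  }
  m <- month_of_doy(doy)
  bm$annual_rate * bm$monthly_shares[m] / days_in_month()[m]
}

#' Heat-attributable deaths for aligned cell-day inputs
#'
#' @param pop Persons per cell (vector or matrix recycled across days).
#' @param daily_rate Deaths per person per day (scalar, per-day vector, or
#'   full cell-by-day matrix).
#' @param rr Relative risk per cell-day (already clamped to >= 1).
#' @param af_convention `"rr_minus_1"` (default, attributable fraction
#'   RR - 1) or `"excess_over_rr"` (the conventional (RR - 1)/RR).
#' @return Deaths, with the shape of `rr`.
#' @export
attributable_deaths <- function(pop, daily_rate, rr,
                                af_convention = c("rr_minus_1", "excess_over_rr")) {
  af_convention <- match.arg(af_convention)
  if (any(pop < 0) || any(daily_rate < 0)) {
    stop("input error: population and rate must be nonnegative", call. = FALSE)
  }
  af <- if (af_convention == "rr_minus_1") rr - 1 else (rr - 1) / rr
  pop * daily_rate * af
}

#' Project heat-attributable deaths for one run
#'
#' Evaluates the generalized relative risk on every cell-day of the
#' temperature series using fixed OT and SMT fields, converts to deaths, and
#' aggregates by year. A run is the basic unit the adaptation scenarios
#' combine: each scenario supplies the (OT, SMT) sources and weights.
#'
#' @param tg A `temp_grid` covering the projection years.
#' @param pop Population matrix on the same lat x lon grid.
#' @param bm A [baseline_mortality()].
#' @param exposure An [exposure_fields()] (or list with `ot`, `smt` matrices)
#'   supplying the OT and SMT fields used in the RR evaluation.
#' @param params A `gen_erf_params`.
#' @param pop_scale National multiplicative population factor for the
#'   projected period (default 1).
#' @param af_convention See [attributable_deaths()].
#' @return An object of class `mortality_result`: `deaths_by_cell_year`
#'   (cells x years matrix, column-major cell order), `annual_totals`,
#'   `decadal_mean` (mean annual total), `years`, `pop` (scaled), and
#'   `warnings` (counters `n_clamped`, `n_smt_above_xint`).
#' @export
project_scenario <- function(tg, pop, bm, exposure, params, pop_scale = 1,
                             af_convention = c("rr_minus_1", "excess_over_rr")) {
  af_convention <- match.arg(af_convention)
  d <- dim(tg)
  if (!all(dim(pop) == d[1:2])) {
    stop("alignment error: population grid does not match temperature grid ",
         "(lat/lon)", call. = FALSE)
  }
  if (!all(dim(exposure$ot) == d[1:2]) || !all(dim(exposure$smt) == d[1:2])) {
    stop("alignment error: exposure fields do not match temperature grid ",
         "(lat/lon)", call. = FALSE)
  }
  years <- attr(tg, "years")
  n_years <- length(years)
  stopifnot(d[3] == 365L * n_years)

  temps <- as_cell_matrix(tg)                   # cells x days
  ot <- as.vector(exposure$ot)
  smt <- as.vector(exposure$smt)
  pop_s <- as.vector(pop) * pop_scale

  rr <- relative_risk(t_day = temps, ot = ot, smt = smt, params = params)
  warn <- list(n_clamped = attr(rr, "n_clamped"),
               n_smt_above_xint = attr(rr, "n_smt_above_xint"))
  rr <- matrix(as.numeric(rr), nrow(temps), ncol(temps))

  rate <- daily_baseline_rate(bm, rep(1:365, times = n_years))
  deaths_day <- attributable_deaths(pop_s, rep(rate, each = nrow(temps)), rr,
                                    af_convention = af_convention)

  year_of_day <- rep(seq_len(n_years), each = 365L)
  deaths_cy <- sapply(seq_len(n_years), function(y) {
    rowSums(deaths_day[, year_of_day == y, drop = FALSE])
  })
  deaths_cy <- matrix(deaths_cy, nrow = nrow(temps), ncol = n_years)
  annual <- colSums(deaths_cy)
  structure(list(deaths_by_cell_year = deaths_cy,
                 annual_totals = stats::setNames(annual, years),
                 decadal_mean = mean(annual),
                 years = years, pop = pop_s, grid_dim = d[1:2],
                 warnings = warn),
            class = "mortality_result")
}

#' Aggregate a projection to states and city boxes
#'
#' @param result A [project_scenario()] result.
#' @param masks Region masks as from [gen_region_masks()]: `state` is a
#'   character matrix assigning every cell a state code; `city_boxes` a
#'   named list of cell-index vectors (column-major).
#' @return List with `state` (data frame: state, deaths_per_year, population,
#'   per_capita_million = deaths/year per million persons) and `city_boxes`
#'   (data frame: city, deaths_per_year).
#' @export
aggregate_regions <- function(result, masks) {
  stopifnot(inherits(result, "mortality_result"))
  state <- as.vector(masks$state)
  pop <- result$pop
  deaths_cell <- rowMeans(result$deaths_by_cell_year)   # mean annual per cell
  if (any(pop > 0 & (is.na(state) | state == ""))) {
    stop("mask error: populated cell with no state assignment", call. = FALSE)
  }
  sdeaths <- tapply(deaths_cell, state, sum)
  spop <- tapply(pop, state, sum)
  state_df <- data.frame(state = names(sdeaths),
                         deaths_per_year = as.numeric(sdeaths),
                         population = as.numeric(spop[names(sdeaths)]),
                         row.names = NULL)
  state_df$per_capita_million <- with(state_df,
    ifelse(population > 0, deaths_per_year / population * 1e6, NA_real_))
  city_df <- data.frame(
    city = names(masks$city_boxes),
    deaths_per_year = vapply(masks$city_boxes,
                             function(ix) sum(deaths_cell[ix]), numeric(1)),
    row.names = NULL
  )
  list(state = state_df, city_boxes = city_df)
}

#' Relative risk looked up from an observed curve
#'
#' Linear interpolation between the 0.1 degC samples; temperatures below OT
#' give RR = 1 (the cold side is out of scope); temperatures above the
#' curve's range hold the last sampled RR (flat extrapolation) and are
#' counted. Values are clamped to >= 1.
#'
#' @param curve An [erf_curve()].
#' @param t_day Daily temperatures, degC.
#' @return RR vector with attribute `n_above_range`.
#' @export
observed_rr <- function(curve, t_day) {
  stopifnot(inherits(curve, "erf_curve"))
  ot <- attr(curve, "ot")
  rr <- stats::approx(curve$temp, curve$rr, xout = t_day, rule = 2)$y
  rr[t_day <= ot] <- 1
  rr <- pmax(1, rr)
  attr(rr, "n_above_range") <- sum(t_day > max(curve$temp))
  rr
}

#' Error table for generalized-vs-observed death columns
#'
#' Given per-city annual average deaths under the generalized and observed
#' curves, computes the absolute error (generalized - observed), the relative
#' error as a rounded percent, and a totals row whose errors are recomputed
#' from the column sums (not summed from the per-city errors).
#'
#' @param city Character vector of city labels.
#' @param generalized,observed Deaths per year under each function.
#' @return Data frame with a final `"Total"` row; columns `city`,
#'   `generalized`, `observed`, `abs_error`, `rel_error_pct`.
#' @export
bias_table <- function(city, generalized, observed) {
  stopifnot(length(city) == length(generalized),
            length(city) == length(observed))
  df <- data.frame(city = as.character(city), generalized = generalized,
                   observed = observed)
  tot <- data.frame(city = "Total", generalized = sum(generalized),
                    observed = sum(observed))
  df <- rbind(df, tot)
  df$abs_error <- df$generalized - df$observed
  df$rel_error_pct <- round(100 * df$abs_error / df$observed)
  df
}

#' Evaluate the generalized function against observed city curves
#'
#' For each city, deaths over the supplied daily temperatures are computed
#' twice -- once with the generalized relative risk (using the city's own OT
#' and SMT) and once by lookup into the observed curve -- and tabulated with
#' absolute and relative errors plus a totals row.
#'
#' @param curves Named list of [erf_curve()] objects.
#' @param params A `gen_erf_params`.
#' @param city_temps Named list (same names) of daily-temperature vectors for
#'   each city's grid box, degC; lengths must be whole 365-day years.
#' @param city_pop Named numeric vector of box populations.
#' @param bm A [baseline_mortality()].
#' @param af_convention See [attributable_deaths()].
#' @return A [bias_table()] data frame with attribute `n_above_range` (count
#'   of observed-curve lookups beyond the sampled range).
#' @export
evaluation_report <- function(curves, params, city_temps, city_pop, bm,
                              af_convention = c("rr_minus_1", "excess_over_rr")) {
  af_convention <- match.arg(af_convention)
  stopifnot(all(names(curves) %in% names(city_temps)),
            all(names(curves) %in% names(city_pop)))
  above <- 0L
  per_city <- lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    t_day <- city_temps[[nm]]
    if (length(t_day) %% 365L != 0L) {
      stop("input error: city temperatures must cover whole years", call. = FALSE)
    }
    n_years <- length(t_day) %/% 365L
    rate <- daily_baseline_rate(bm, rep(1:365, times = n_years))
    rr_g <- relative_risk(t_day, ot = attr(cv, "ot"), smt = attr(cv, "smt"),
                          params = params)
    rr_o <- observed_rr(cv, t_day)
    above <<- above + attr(rr_o, "n_above_range")
    c(gen = sum(attributable_deaths(city_pop[[nm]], rate, as.numeric(rr_g),
                                    af_convention)) / n_years,
      obs = sum(attributable_deaths(city_pop[[nm]], rate, as.numeric(rr_o),
                                    af_convention)) / n_years)
  })
  m <- do.call(rbind, per_city)
  out <- bias_table(names(curves), m[, "gen"], m[, "obs"])
  attr(out, "n_above_range") <- above
  out
}
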