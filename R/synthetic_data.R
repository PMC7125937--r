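# Synthetic inputs: gridded daily temperature, population, monthly mortality
# weights, region masks, and city exposure-response curves with known truth.
# These emulate the statistical structure of the real inputs (bias-corrected
# GCM daily fields, gridded population, seasonally weighted mortality) so that
# every downstream stage can be exercised and checked against ground truth.

#' Specification for a synthetic gridded daily temperature field
#'
#' Cells receive an annual-mean temperature that varies linearly with the
#' latitude index (warm "south" row to cool "north" row), a sinusoidal
#' seasonal cycle peaking in mid-July, AR(1) day-to-day noise, and a linear
#' warming trend across years.
#'
#' @param n_lat,n_lon Grid dimensions (cell counts).
#' @param years Contiguous calendar years covered by the series.
#' @param annual_mean Domain-average annual-mean temperature, degC.
#' @param lat_range Spread of annual means across latitude rows, degC
#'   (row 1 is the warmest; 0 gives a spatially uniform mean).
#' @param seasonal_amplitude Amplitude of the seasonal sinusoid, degC.
#' @param ar1_coef AR(1) coefficient of the daily residuals, in (-1, 1).
#' @param daily_sd Stationary (marginal) standard deviation of the daily
#'   residuals, degC.
#' @param trend Linear warming trend, degC per decade, applied uniformly to
#'   all days relative to `ref_year`.
#' @param ref_year Year at which the trend offset is zero; defaults to the
#'   first year of `years`. Setting it earlier lets a future decade be
#'   generated consistently with a reference decade.
#' @param peak_doy Day-of-year at which the seasonal cycle peaks (default 196,
#'   mid-July, Northern-Hemisphere convention).
#' @param smt_band Plausibility band for per-cell summer (JJA) mean
#'   temperatures, degC; generation warns if defaults produce cells outside.
#' @param seed Integer seed; identical specs give bit-identical fields.
#' @return An object of class `climate_spec`.
#' @export
climate_spec <- function(n_lat = 10L, n_lon = 10L, years = 2010:2019,
                         annual_mean = 16, lat_range = 8,
                         seasonal_amplitude = 10, ar1_coef = 0.7,
                         daily_sd = 3, trend = 0, ref_year = years[1],
                         peak_doy = 196L, smt_band = c(18, 32), seed = 1L) {
  if (n_lat < 1L || n_lon < 1L) {
    stop("configuration error: grid dimensions must be positive", call. = FALSE)
  }
  if (length(years) < 1L) {
    stop("configuration error: `years` must be non-empty", call. = FALSE)
  }
  if (length(years) > 1L && any(diff(years) != 1L)) {
    stop("configuration error: `years` must be contiguous", call. = FALSE)
  }
  if (!is.finite(daily_sd) || daily_sd < 0) {
    stop("configuration error: `daily_sd` must be >= 0", call. = FALSE)
  }
  if (abs(ar1_coef) >= 1) {
    stop("configuration error: |ar1_coef| must be < 1", call. = FALSE)
  }
  structure(
    list(n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
         years = as.integer(years), annual_mean = annual_mean,
         lat_range = lat_range, seasonal_amplitude = seasonal_amplitude,
         ar1_coef = ar1_coef, daily_sd = daily_sd, trend = trend,
         ref_year = as.integer(ref_year), peak_doy = as.integer(peak_doy),
         smt_band = smt_band, seed = as.integer(seed)),
    class = "climate_spec"
  )
}

#' Generate a gridded daily temperature series
#'
#' One value per cell per calendar day of the no-leap year:
#' cell mean + seasonal sinusoid + AR(1) residual + trend offset. The AR(1)
#' residual is initialized from its stationary distribution, so the series is
#' stationary from the first day.
#'
#' @param spec A [climate_spec()].
#' @return A `temp_grid`: numeric array with dim `(n_lat, n_lon, 365 * n_years)`
#'   and attributes `years`, `peak_doy`, `units = "degC"`.
#' @export
gen_temperature_grid <- function(spec) {
  stopifnot(inherits(spec, "climate_spec"))
  n_cell <- spec$n_lat * spec$n_lon
  n_years <- length(spec$years)
  n_days <- 365L * n_years

  cell_mean <- if (spec$n_lat > 1L) {
    spec$annual_mean + spec$lat_range * (0.5 - (seq_len(spec$n_lat) - 1) / (spec$n_lat - 1))
  } else {
    rep(spec$annual_mean, 1L)
  }
  cell_mean <- matrix(cell_mean, spec$n_lat, spec$n_lon) # constant along lon

  doy <- rep(1:365, times = n_years)
  season <- spec$seasonal_amplitude * cos(2 * pi * (doy - spec$peak_doy) / 365)
  year_of_day <- rep(spec$years, each = 365L)
  trend_off <- spec$trend * (year_of_day - spec$ref_year) / 10

  # AR(1) residuals per cell, stationary marginal sd = daily_sd
  resid <- matrix(0, n_cell, n_days)
  if (spec$daily_sd > 0) {
    set.seed(spec$seed)
    innov_sd <- spec$daily_sd * sqrt(1 - spec$ar1_coef^2)
    eps <- matrix(stats::rnorm(n_cell * n_days, sd = innov_sd), n_cell, n_days)
    resid[, 1] <- stats::rnorm(n_cell, sd = spec$daily_sd)
    for (d in 2:n_days) {
      resid[, d] <- spec$ar1_coef * resid[, d - 1] + eps[, d]
    }
  }

  base <- outer(as.vector(cell_mean), season + trend_off, "+")
  x <- array(base + resid, dim = c(spec$n_lat, spec$n_lon, n_days))
  tg <- structure(x, years = spec$years, peak_doy = spec$peak_doy,
                  units = "degC", class = c("temp_grid", "array"))

  smt <- compute_smt(tg)
  if (any(smt < spec$smt_band[1]) || any(smt > spec$smt_band[2])) {
    warning(sprintf("generated JJA means fall outside the [%g, %g] degC band",
                    spec$smt_band[1], spec$smt_band[2]), call. = FALSE)
  }
  tg
}

#' Specification for one synthetic city exposure-response curve
#'
#' The curve is generated from a known generalized-function truth: the
#' quadratic coefficient is `slope_a_true * (smt_true - xint_a_true)` and the
#' linear coefficient `slope_b_true * (smt_true - xint_b_true)`, so re-fitting
#' a set of such cities should recover the generating slopes and x-intercepts.
#'
#' @param smt_true Summer mean temperature of the city, degC.
#' @param slope_a_true,xint_a_true Slope (per degC^3) and x-intercept (degC)
#'   of the quadratic-coefficient-vs-SMT line.
#' @param slope_b_true,xint_b_true Slope (per degC^2) and x-intercept (degC)
#'   of the linear-coefficient-vs-SMT line.
#' @param noise_sd I.i.d. Gaussian noise on the sampled relative risks
#'   (RR units); samples are clamped to be nonnegative.
#' @param t_range Extent of the curve above the optimal temperature, degC.
#' @param ot Optimal temperature of the city, degC; defaults to
#'   `smt_true + 3`, a typical gap between the JJA mean and the annual 84th
#'   percentile.
#' @param city_id Label carried through to the curve.
#' @param seed Integer seed for the noise.
#' @return An object of class `synthetic_city_spec`.
#' @export
synthetic_city_spec <- function(smt_true, slope_a_true = -0.0014,
                                xint_a_true = 30.9, slope_b_true = 0.005,
                                xint_b_true = 26.7, noise_sd = 0,
                                t_range = 10, ot = smt_true + 3,
                                city_id = "city", seed = 1L) {
  if (!is.finite(t_range) || t_range <= 0) {
    stop("configuration error: `t_range` must be > 0", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("configuration error: `noise_sd` must be >= 0", call. = FALSE)
  }
  structure(
    list(smt_true = smt_true, slope_a_true = slope_a_true,
         xint_a_true = xint_a_true, slope_b_true = slope_b_true,
         xint_b_true = xint_b_true, noise_sd = noise_sd, t_range = t_range,
         ot = ot, city_id = city_id, seed = as.integer(seed)),
    class = "synthetic_city_spec"
  )
}

#' Generate a city exposure-response curve from known truth
#'
#' Samples relative risk at 0.1 degC increments from the optimal temperature
#' (OT) to OT + `t_range`. Noise-free curves satisfy RR = 1 exactly at OT.
#'
#' @param spec A [synthetic_city_spec()].
#' @return An [erf_curve()] with the generating truth attached as attribute
#'   `truth` (list of the true quadratic and linear coefficients).
#' @export
gen_city_erf <- function(spec) {
  stopifnot(inherits(spec, "synthetic_city_spec"))
  a_true <- spec$slope_a_true * (spec$smt_true - spec$xint_a_true)
  b_true <- spec$slope_b_true * (spec$smt_true - spec$xint_b_true)
  tt <- seq(0, spec$t_range, by = 0.1)
  rr <- 1 + a_true * tt^2 + b_true * tt
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    rr <- rr + stats::rnorm(length(tt), sd = spec$noise_sd)
  }
  rr <- pmax(rr, 0)
  curve <- erf_curve(city_id = spec$city_id, smt = spec$smt_true,
                     ot = spec$ot, temp = spec$ot + tt, rr = rr)
  attr(curve, "truth") <- list(a = a_true, b = b_true)
  curve
}

#' Generate a gridded population that sums exactly to a target
#'
#' Cell weights are drawn uniformly and converted to integer persons by
#' largest-remainder apportionment, so the grid total equals `total_persons`
#' exactly.
#'
#' @param n_lat,n_lon Grid dimensions.
#' @param total_persons Positive integer total population.
#' @param seed Integer seed.
#' @return Numeric matrix `(n_lat, n_lon)` of nonnegative integers.
#' @export
gen_population_grid <- function(n_lat, n_lon, total_persons, seed = 1L) {
  if (total_persons <= 0) {
    stop("configuration error: `total_persons` must be > 0", call. = FALSE)
  }
  set.seed(seed)
  w <- stats::runif(n_lat * n_lon)
  ideal <- w / sum(w) * total_persons
  base <- floor(ideal)
  short <- round(total_persons - sum(base))
  if (short > 0) {
    extra <- order(ideal - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  matrix(base, n_lat, n_lon)
}

#' Monthly mortality shares with a winter excess
#'
#' Daily weights follow `1 + winter_excess * cos(2*pi*(d - 15)/365)` (peak at
#' mid-January), summed within months and normalized to 1. With
#' `winter_excess = 0` each month's share is proportional to its day count,
#' i.e. deaths are uniform across the year.
#'
#' @param winter_excess Fractional amplitude of the seasonal cycle in daily
#'   mortality, in [0, 1).
#' @return Numeric vector of 12 positive shares summing to 1.
#' @export
gen_monthly_weights <- function(winter_excess = 0.15) {
  if (winter_excess < 0 || winter_excess >= 1) {
    stop("configuration error: `winter_excess` must be in [0, 1)", call. = FALSE)
  }
  d <- 1:365
  w <- 1 + winter_excess * cos(2 * pi * (d - 15) / 365)
  shares <- as.vector(tapply(w, month_of_doy(d), sum)) / sum(w)
  names(shares) <- month.abb
  shares
}

#' Simple region masks: state bands and city grid boxes
#'
#' States are contiguous latitude bands covering every cell; city boxes are
#' single cells spread over the grid (a stand-in for the 0.5-degree boxes
#' centered on observed cities).
#'
#' @param n_lat,n_lon Grid dimensions.
#' @param n_states Number of latitude-band states (capped at `n_lat`).
#' @param city_cells Optional integer vector of cell indices (column-major)
#'   to use as one-cell city boxes; default places cities on the grid
#'   diagonal.
#' @return List with `state` (character matrix of state codes) and
#'   `city_boxes` (named list of integer cell-index vectors).
#' @export
gen_region_masks <- function(n_lat, n_lon, n_states = 4L, city_cells = NULL) {
  n_states <- min(n_states, n_lat)
  band <- cut(seq_len(n_lat), breaks = n_states, labels = FALSE)
  state <- matrix(sprintf("S%02d", band), n_lat, n_lon)
  if (is.null(city_cells)) {
    k <- min(n_lat, n_lon)
    city_cells <- (seq_len(k) - 1L) * n_lat + seq_len(k)
  }
  boxes <- as.list(city_cells)
  names(boxes) <- sprintf("C%02d", seq_along(boxes))
  list(state = state, city_boxes = boxes)
}

#' Write a temperature grid as a long-format CSV
#'
#' Columns `lat_idx`, `lon_idx`, `day`, `temp_degc`. Intended for small grids
#' and interchange; large fields stay in memory.
#'
#' @param tg A `temp_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_temp_grid_csv <- function(tg, path) {
  d <- dim(tg)
  df <- data.frame(
    lat_idx = rep(seq_len(d[1]), times = d[2] * d[3]),
    lon_idx = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    day = rep(seq_len(d[3]), each = d[1] * d[2]),
    temp_degc = as.vector(tg)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
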