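# Exposure fields: per-cell optimal temperature (OT) and summer mean
# temperature (SMT) derived from gridded daily temperatures for a period.
# The local OT is taken to be the 84th percentile of the full annual daily
# temperature distribution; the SMT is the June--August mean.

#' Per-cell optimal temperature from daily temperatures
#'
#' The OT of each cell is a percentile (default the 84th) of that cell's
#' daily temperature distribution over the whole period, computed with
#' linear interpolation between closest order statistics (the "type 7"
#' convention).
#'
#' @param tg A `temp_grid` (array lat x lon x day), or a matrix
#'   `cells x days`.
#' @param percentile Percentile in (0, 100], default 84.
#' @param max_missing Maximum tolerated fraction of missing values per cell
#'   (default 0.05); cells above it raise a data-quality error naming them.
#' @return Numeric matrix (lat x lon) of OTs, degC (or a vector for matrix
#'   input).
#' @export
compute_ot <- function(tg, percentile = 84, max_missing = 0.05) {
  stopifnot(percentile > 0, percentile <= 100)
  m <- as_cell_matrix(tg)
  if (ncol(m) < 365L) {
    stop("input error: need at least 365 daily values per cell", call. = FALSE)
  }
  miss <- rowMeans(is.na(m))
  if (any(miss > max_missing)) {
    stop("data-quality error: cells with too many missing values: ",
         paste(which(miss > max_missing), collapse = ", "), call. = FALSE)
  }
  ot <- apply(m, 1, stats::quantile, probs = percentile / 100,
              type = 7, names = FALSE, na.rm = TRUE)
  reshape_like(ot, tg)
}

#' Per-cell summer (June--August) mean temperature
#'
#' @param tg A `temp_grid` whose day dimension covers whole no-leap years,
#'   or a matrix `cells x days` with days starting on January 1.
#' @return Numeric matrix (lat x lon) of SMTs, degC (or a vector for matrix
#'   input).
#' @export
compute_smt <- function(tg) {
  m <- as_cell_matrix(tg)
  n_days <- ncol(m)
  if (n_days %% 365L != 0L) {
    stop("input error: day dimension must cover whole 365-day years",
         call. = FALSE)
  }
  n_years <- n_days %/% 365L
  doy <- rep(1:365, times = n_years)
  jja <- doy %in% jja_doys()
  if (!any(jja)) {
    stop("input error: no June--August days in period", call. = FALSE)
  }
  smt <- rowMeans(m[, jja, drop = FALSE])
  reshape_like(smt, tg)
}

#' Derive OT and SMT exposure fields for a period
#'
#' @param tg A `temp_grid`.
#' @param period Two-element `(first_year, last_year)` to subset from the
#'   grid's years; default the full series.
#' @param percentile OT percentile, default 84.
#' @param scenario_label Free-text label carried in the result.
#' @return An object of class `exposure_fields`: list with `ot` and `smt`
#'   matrices, `period`, `percentile`, `scenario_label`.
#' @export
exposure_fields <- function(tg, period = NULL, percentile = 84,
                            scenario_label = "") {
  years <- attr(tg, "years")
  if (is.null(period)) period <- range(years)
  keep_years <- years >= period[1] & years <= period[2]
  if (!any(keep_years)) {
    stop("input error: period outside the grid's years", call. = FALSE)
  }
  day_keep <- rep(keep_years, each = 365L)
  sub <- tg[, , day_keep, drop = FALSE]
  attr(sub, "years") <- years[keep_years]
  class(sub) <- c("temp_grid", "array")
  ot <- compute_ot(sub, percentile = percentile)
  smt <- compute_smt(sub)
  if (any(!is.finite(ot)) || any(!is.finite(smt))) {
    stop("input error: non-finite exposure fields", call. = FALSE)
  }
  if (any(smt < -90) || any(smt > 60)) {
    stop("input error: SMT outside [-90, 60] degC sanity bounds", call. = FALSE)
  }
  structure(list(ot = ot, smt = smt, period = period,
                 percentile = percentile, scenario_label = scenario_label),
            class = "exposure_fields")
}

# Internal: view a temp_grid (lat, lon, day) as a cells x days matrix, or
# pass a matrix through unchanged.
as_cell_matrix <- function(tg) {
  if (is.matrix(tg)) return(tg)
  d <- dim(tg)
  stopifnot(length(d) == 3L)
  dim(tg) <- c(d[1] * d[2], d[3])
  unclass(tg)
}

# Internal: reshape a per-cell vector back to the grid's lat x lon layout.
reshape_like <- function(x, tg) {
  if (is.matrix(tg)) return(x)
  d <- dim(tg)
  matrix(x, d[1], d[2])
}
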