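# 365-day (no-leap) calendar helpers. All gridded series in this package use
# a no-leap calendar, the convention of most climate-model archives.

#' Days in each month (no-leap calendar)
#'
#' @return Integer vector of length 12.
#' @export
days_in_month <- function() {
  c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
}

#' Month index for each day of a 365-day year
#'
#' @param doy Day-of-year, integer in 1..365.
#' @return Integer month (1..12) for each element of `doy`.
#' @export
month_of_doy <- function(doy) {
  stopifnot(all(doy >= 1L), all(doy <= 365L))
  ends <- cumsum(days_in_month())
  findInterval(doy - 1L, c(0L, ends), rightmost.closed = TRUE)
}

#' Day-of-year indices for June--August
#'
#' June 1 is day 152 and August 31 day 243 in the no-leap calendar.
#'
#' @return Integer vector of JJA day-of-year indices.
#' @export
jja_doys <- function() {
  152L:243L
}
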