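# Calendar conventions.
#
# Day-of-year (DOY) is computed within each observation's own calendar year,
# so Feb 29 is DOY 60 in leap years. Reporting utilities that map between
# month-day labels and DOY use the non-leap convention (June 10 <-> 161,
# August 18 <-> 230) unless asked for the leap variant. The half-year split
# used by the individual-inclusion rule is June 30 = DOY 181 (non-leap).

#' Day of year for a date
#'
#' @param date A `Date` vector.
#' @return Integer DOY, 1--366, computed within each date's own calendar year.
#' @export
date_to_doy <- function(date) {
  as.integer(format(as.Date(date), "%j"))
}

#' Convert a day-of-year to a calendar date label
#'
#' Uses a reference (non-leap by default) year, so `doy_to_date(161)` is
#' June 10 and `doy_to_date(230)` is August 18.
#'
#' @param doy Integer DOY in 1--365 (366 with `leap = TRUE`).
#' @param leap Use a leap reference year?
#' @return A `Date` in the reference year (2019 non-leap, 2020 leap).
#' @export
doy_to_date <- function(doy, leap = FALSE) {
  ref <- if (leap) as.Date("2020-01-01") else as.Date("2019-01-01")
  ndays <- if (leap) 366L else 365L
  doy <- as.integer(doy)
  if (any(doy < 1 | doy > ndays)) {
    abort(sprintf("`doy` must lie in 1..%d", ndays))
  }
  ref + (doy - 1L)
}

#' Month-day label ("Mar 13") for a DOY, non-leap convention
#' @param doy Integer DOY.
#' @param leap Use a leap reference year?
#' @return Character month-day labels.
#' @export
doy_label <- function(doy, leap = FALSE) {
  format(doy_to_date(doy, leap = leap), "%b %d")
}

# circular difference a - b on a circle of given period, result in
# (-period/2, period/2]
circ_diff <- function(a, b, period = 366) {
  d <- (a - b) %% period
  if_else(d > period / 2, d - period, d)
}

# unsigned circular distance
circ_dist <- function(a, b, period = 366) {
  abs(circ_diff(a, b, period = period))
}
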