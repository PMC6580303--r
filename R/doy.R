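#' Day-of-year utilities
#'
#' All phenology in this package lives on a circular day-of-year (DOY) axis
#' of 366 days, so dates from leap and non-leap years share one calendar
#' circle. `doy()` maps calendar dates to DOY; `doy_date()` inverts the
#' mapping for a given year; `circ_diff()` is the signed circular
#' difference between two DOYs, mapped to `(-183, 183]` with positive
#' values meaning `b` falls later in the season than `a`.
#'
#' @param date A `Date` vector (or something coercible via `as.Date()`).
#' @return `doy()`: integer vector in `[1, 366]`.
#' @examples
#' doy(as.Date("2000-12-31")) # 366 (leap year)
#' circ_diff(350, 10)         # +26: wraps across the new year
#' @export
doy <- function(date) {
  date <- as.Date(date)
  as.integer(as.POSIXlt(date)$yday) + 1L
}

#' @rdname doy
#' @param d Integer day-of-year in `[1, 366]`.
#' @param year Calendar year used to realise the date. Day 366 in a
#'   non-leap year is clamped to 31 December.
#' @export
doy_date <- function(d, year) {
  stopifnot(all(d >= 1), all(d <= DOY_CIRCLE))
  if (length(d) == 0) return(as.Date(character()))
  jan1 <- as.Date(paste0(year, "-01-01"))
  dec31 <- as.Date(paste0(year, "-12-31"))
  pmin(jan1 + (d - 1), dec31)
}

#' @rdname doy
#' @param a,b Day-of-year values (numeric).
#' @export
circ_diff <- function(a, b) {
  ((b - a + 182) %% DOY_CIRCLE) - 182
}
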