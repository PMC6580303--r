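#' Circular kernel density of an event phenology
#'
#' Estimates a normalized seasonal density over day-of-year from dated
#' events (optionally count-weighted) by Gaussian kernel smoothing on the
#' 366-day circle. The circular support is realised by replicating each
#' event at plus and minus one full circle and renormalizing the density on
#' the unit-day grid `1:366`, so mass cannot leak off the calendar edges
#' for seasons that straddle the new year.
#'
#' Bandwidth `"auto"` applies Silverman's rule-of-thumb to the (weight-
#' expanded) unwrapped sample, floored at 3 days; events concentrated on a
#' single day carry no spread information, so `"auto"` then asks for an
#' explicit bandwidth instead of guessing.
#'
#' @param events Numeric vector of day-of-year values in `[1, 366]`.
#' @param bandwidth Kernel standard deviation in days, or `"auto"`.
#' @param weights Optional nonnegative integer weights (e.g. daily counts);
#'   default 1 per event.
#' @return A `phenology_density` object: list with `grid` (`1:366`),
#'   `values` (density per day, summing to 1), `bandwidth` and `n_events`.
#' @examples
#' d <- estimate_density(c(200, 210, 240, 250), bandwidth = 10)
#' peak_doy(d)
#' @export
estimate_density <- function(events, bandwidth = "auto", weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(events))
  stopifnot(length(weights) == length(events), all(weights >= 0))
  keep <- weights > 0
  events <- events[keep]
  weights <- weights[keep]
  if (sum(weights) == 0 || length(events) == 0) {
    stop("all event weights are zero", call. = FALSE)
  }
  if (any(events < 1 | events > DOY_CIRCLE)) {
    stop("events must be days-of-year in [1, 366]", call. = FALSE)
  }
  distinct <- length(unique(events))
  if (identical(bandwidth, "auto")) {
    if (distinct < 2) {
      stop("events fall on a single day; supply an explicit bandwidth",
           call. = FALSE)
    }
    expanded <- rep(events, times = round(weights))
    bandwidth <- max(stats::bw.nrd0(expanded), 3)
  }
  stopifnot(is.numeric(bandwidth), bandwidth > 0)
  grid <- seq_len(DOY_CIRCLE)
  # wrapped kernel: events replicated at x + m * 366 for enough circles
  # that the omitted tails are negligible even for very wide kernels
  n_copies <- max(1, ceiling(3 * bandwidth / DOY_CIRCLE))
  delta <- outer(grid, events, "-")
  k <- 0
  for (m in -n_copies:n_copies) {
    k <- k + stats::dnorm(delta + m * DOY_CIRCLE, sd = bandwidth)
  }
  values <- as.numeric(k %*% weights)
  values <- values / sum(values)
  structure(list(grid = grid, values = values, bandwidth = bandwidth,
                 n_events = sum(weights)),
            class = "phenology_density")
}

#' @export
print.phenology_density <- function(x, ...) {
  cat("<phenology_density> ", x$n_events, " events, bandwidth ",
      signif(x$bandwidth, 4), " days, peak at day ", peak_doy(x), "\n",
      sep = "")
  invisible(x)
}

#' Relative seasonal density of a detection series
#'
#' Transforms a detection series (counts of individuals detected per day or
#' week) into a relative density over day-of-year: counts act as kernel
#' weights on their observation day, so the result is invariant to the
#' overall count scale and comparable across monitoring efforts.
#'
#' @param series Detection tibble with `date` and `count` columns
#'   ([read_detections()] or [gen_detections()] output).
#' @inheritParams estimate_density
#' @return A `phenology_density`.
#' @export
relative_density <- function(series, bandwidth = "auto") {
  if (sum(series$count) <= 0) {
    stop("detection series has no positive counts", call. = FALSE)
  }
  estimate_density(doy(series$date), bandwidth = bandwidth,
                   weights = series$count)
}

#' Cumulative seasonal distribution
#'
#' Accumulates a phenology density from a stated origin day, wrapping once
#' around the calendar circle, so the final value is 1.
#'
#' @param density A `phenology_density`.
#' @param origin Day-of-year where accumulation starts (default 1).
#' @return A `phenology_cdf`: list with `grid` (days in unwrapped order
#'   from `origin`), `values` (non-decreasing, ending at 1) and `origin`.
#' @export
to_cdf <- function(density, origin = 1L) {
  stopifnot(inherits(density, "phenology_density"),
            origin >= 1, origin <= DOY_CIRCLE)
  ord <- ((seq_len(DOY_CIRCLE) - 1 + origin - 1) %% DOY_CIRCLE) + 1
  structure(list(grid = ord, values = cumsum(density$values[ord]),
                 origin = as.integer(origin)),
            class = "phenology_cdf")
}

#' @export
print.phenology_cdf <- function(x, ...) {
  cat("<phenology_cdf> origin day ", x$origin, ", final mass ",
      signif(tail(x$values, 1), 6), "\n", sep = "")
  invisible(x)
}

#' Peak day of a phenology density
#'
#' The grid argmax; ties are broken by the earliest day after day 1.
#'
#' @param density A `phenology_density`.
#' @return Integer day-of-year.
#' @export
peak_doy <- function(density) {
  stopifnot(inherits(density, "phenology_density"))
  density$grid[which.max(density$values)]
}

#' Median day of a phenology density
#'
#' The first day at which the cumulative mass from `origin` reaches 0.5.
#'
#' @inheritParams to_cdf
#' @return Integer day-of-year.
#' @export
median_doy <- function(density, origin = 1L) {
  cdf <- to_cdf(density, origin)
  cdf$grid[which(cdf$values >= 0.5)[1]]
}

#' Circular timing lag between two phenologies
#'
#' Signed circular difference (in days, mapped to `(-183, 183]`) between
#' the timing statistic of `b` and that of `a`; positive means `b` occurs
#' later in the season than `a`.
#'
#' @param a,b `phenology_density` objects.
#' @param statistic `"peak"` (density argmax) or `"median"` (day where the
#'   CDF from day 1 reaches 0.5).
#' @return Signed number of days.
#' @export
phenology_lag <- function(a, b, statistic = c("peak", "median")) {
  statistic <- match.arg(statistic)
  f <- switch(statistic, peak = peak_doy, median = median_doy)
  circ_diff(f(a), f(b))
}

#' Export a density or CDF as two-column delimited text
#'
#' @param x A `phenology_density` or `phenology_cdf`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_phenology <- function(x, path) {
  readr::write_csv(tibble::tibble(day = x$grid, value = x$values), path)
  invisible(path)
}
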