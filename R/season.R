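## mean Gregorian month, used to express window lengths in months
MONTH_DAYS <- 30.44

#' Configuration for the date-perturbing seasonal bootstrap
#'
#' Controls the within-bin bootstrap that estimates the core seasonal
#' window of shark-bitten strandings. Each resampled record's date is
#' perturbed by a truncated normal centred on the observed date, with a
#' scale fitted to the median absolute deviation (MAD, unscaled) of the
#' bin's observed dates and shrunk with the bin's sample size, so bins
#' with many strandings stay tightly constrained to the observed data
#' while sparse bins explore more of the calendar.
#'
#' @param n_replicates Bootstrap replicates per bin (default 1,000).
#' @param coverage Central mass of the seasonal window (default 0.80, the
#'   core 80% interval).
#' @param sd_rule How the bin MAD is scaled into the perturbation sigma:
#'   `"mad_over_sqrt_n"` (default, standard-error-like), `"mad_over_n"`,
#'   or `"mad"` (unscaled).
#' @param sd_floor Minimum sigma in days (default 1); also the sigma used
#'   when the MAD is undefined (single-record bin).
#' @param truncation_halfwidth Half-width of the truncation interval
#'   around each observed date, in days (default 365).
#' @param seed Optional integer seed for exact reproducibility.
#' @return A list of class `perturbation_config`.
#' @export
perturbation_config <- function(n_replicates = 1000L, coverage = 0.80,
                                sd_rule = c("mad_over_sqrt_n", "mad_over_n",
                                            "mad"),
                                sd_floor = 1, truncation_halfwidth = 365,
                                seed = NULL) {
  sd_rule <- match.arg(sd_rule)
  stopifnot(coverage > 0, coverage < 1, sd_floor > 0,
            truncation_halfwidth >= sd_floor, n_replicates >= 1)
  structure(list(n_replicates = as.integer(n_replicates), coverage = coverage,
                 sd_rule = sd_rule, sd_floor = sd_floor,
                 truncation_halfwidth = truncation_halfwidth, seed = seed),
            class = "perturbation_config")
}

#' Circular median absolute deviation of day-of-year values
#'
#' Raw (unscaled) MAD of seasonal timing on the 366-day circle: signed
#' deviations are taken from the sample's circular mean direction via the
#' shortest arc, re-centred on their median, and the median absolute
#' re-centred deviation is returned. Working on the circle keeps the
#' spread estimate seasonal -- it is not inflated by the year-to-year
#' spacing of dates within a multi-year bin, nor by seasons that straddle
#' the new year.
#'
#' @param doys Numeric day-of-year values.
#' @return MAD in days.
#' @export
circ_mad <- function(doys) {
  ang <- doys / DOY_CIRCLE * 2 * pi
  mu <- atan2(mean(sin(ang)), mean(cos(ang)))
  mu_doy <- (mu / (2 * pi) * DOY_CIRCLE) %% DOY_CIRCLE
  dev <- circ_diff(mu_doy, doys)
  median(abs(dev - median(dev)))
}

#' Perturbation sigma for a bin of observed stranding dates
#'
#' `sigma = max(sd_floor, MAD / scale(n))` where the MAD is the raw
#' circular median absolute deviation of the bin's dates on the
#' day-of-year axis ([circ_mad()]) and `scale(n)` is `sqrt(n)`, `n` or 1
#' per the configured rule. The seasonal (day-of-year) axis is essential
#' here: within a multi-year bin the spread of raw calendar dates is
#' dominated by which year a stranding fell in, not by its seasonal
#' timing, and it is the seasonal timing the perturbation is meant to
#' emulate. A single-record bin has no MAD; its sigma is the floor.
#'
#' @param dates `Date` vector of a bin's observed shark-cause strandings.
#' @param cfg A [perturbation_config()].
#' @return Sigma in days.
#' @export
bin_sigma <- function(dates, cfg = perturbation_config()) {
  n <- length(dates)
  if (n == 0) stop("bin has no records", call. = FALSE)
  if (n == 1) return(cfg$sd_floor)
  m <- circ_mad(doy(as.Date(dates)))
  scale <- switch(cfg$sd_rule,
                  mad_over_sqrt_n = sqrt(n),
                  mad_over_n = n,
                  mad = 1)
  max(cfg$sd_floor, m / scale)
}

## truncated-normal draw centred at `centre` (numeric days), sd `sigma`,
## truncated to centre +/- halfwidth; inverse-CDF sampling, vectorised
rtrunc_centre <- function(centre, sigma, halfwidth) {
  lo <- pnorm(-halfwidth / sigma)
  hi <- pnorm(halfwidth / sigma)
  u <- runif(length(centre), lo, hi)
  centre + sigma * qnorm(u)
}

#' Perturb observed stranding dates with a truncated normal
#'
#' Draws one adjusted date per input record from a normal centred on the
#' observed date with the bin's sigma (see [bin_sigma()]), truncated to
#' the observed date plus/minus the configured half-width. This is the
#' date-adjustment step of the seasonal bootstrap: it produces realistic
#' temporal spread without oversampling exact observed dates.
#'
#' @inheritParams bin_sigma
#' @param sigma Perturbation sigma in days; defaults to the bin's own
#'   [bin_sigma()].
#' @return A `Date` vector of adjusted dates (rounded to whole days).
#' @export
perturb_dates <- function(dates, cfg = perturbation_config(),
                          sigma = bin_sigma(dates, cfg)) {
  if (length(dates) == 0) stop("bin has no records", call. = FALSE)
  adj <- rtrunc_centre(as.numeric(as.Date(dates)), sigma,
                       cfg$truncation_halfwidth)
  as.Date(round(adj), origin = "1970-01-01")
}

#' Bootstrap-with-perturbation replicates for one bin
#'
#' Each replicate resamples the bin's records with replacement (replicate
#' size = observed size) and perturbs every drawn date with the bin's
#' truncated-normal adjustment. Under the default sigma rule, larger bins
#' yield replicate distributions that hug the observed dates more tightly.
#'
#' @inheritParams bin_sigma
#' @return A tibble with columns `replicate` and `doy` (adjusted
#'   day-of-year, wrapped), `n_replicates * length(dates)` rows.
#' @export
resample_bin <- function(dates, cfg = perturbation_config()) {
  n <- length(dates)
  if (n == 0) stop("bin has no records", call. = FALSE)
  sigma <- bin_sigma(dates, cfg)
  R <- cfg$n_replicates
  run <- function() {
    t0 <- as.numeric(as.Date(dates))
    idx <- sample.int(n, n * R, replace = TRUE)
    adj <- rtrunc_centre(t0[idx], sigma, cfg$truncation_halfwidth)
    tibble::tibble(replicate = rep(seq_len(R), each = n),
                   doy = doy(as.Date(round(adj), origin = "1970-01-01")))
  }
  if (is.null(cfg$seed)) run() else {
    withr::with_seed(stage_seed(cfg$seed, "resample_bin"), run())
  }
}

#' Core seasonal interval of a day-of-year sample
#'
#' The central `coverage` interval of the sample, computed on a linear
#' axis unwrapped from `origin` (type-7 quantiles): start at the
#' `(1 - coverage)/2` quantile, end at the `1 - (1 - coverage)/2`
#' quantile.
#'
#' @param doys Numeric day-of-year sample (length >= 2).
#' @param coverage Central mass in (0, 1); default 0.80.
#' @param origin Day-of-year where the linear axis begins (default 1).
#' @return Named numeric: `start`, `end` (days on the unwrapped axis from
#'   `origin`; may exceed 366 when the window wraps) and `length_days`.
#' @export
core_interval <- function(doys, coverage = 0.80, origin = 1L) {
  if (coverage <= 0 || coverage >= 1) {
    stop("coverage must be in (0, 1)", call. = FALSE)
  }
  if (length(doys) < 2) stop("need at least 2 values", call. = FALSE)
  shifted <- (doys - origin) %% DOY_CIRCLE
  a <- (1 - coverage) / 2
  q <- quantile(shifted, c(a, 1 - a), names = FALSE, type = 7)
  c(start = origin + q[1], end = origin + q[2], length_days = q[2] - q[1])
}

#' Per-bin core seasonal window estimates
#'
#' For every multi-year bin of shark-attributed strandings, runs the
#' bootstrap-with-perturbation ([resample_bin()]) and computes the core
#' `coverage` interval and median day of each replicate. Per-bin summaries
#' are the medians of the replicate endpoints; window length is reported
#' in days and in mean Gregorian months (30.44 days). Bins with fewer than
#' 2 records are flagged low-confidence.
#'
#' @param records Stranding tibble with `bin` and `date` columns,
#'   restricted to shark-attributed records.
#' @param cfg A [perturbation_config()].
#' @param origin Day-of-year origin of the linear interval axis.
#' @return A list of class `season_estimate`: `summary` (one row per bin:
#'   `bin`, `n_records`, `start_doy`, `end_doy`, `length_days`,
#'   `length_months`, `low_confidence`) and `replicates` (`bin`,
#'   `replicate`, `start`, `end`, `length_days`, `median_doy`).
#' @export
season_by_bin <- function(records, cfg = perturbation_config(), origin = 1L) {
  if (nrow(records) == 0) stop("no shark-attributed records in any bin",
                               call. = FALSE)
  bins <- sort(unique(records$bin))
  reps <- list()
  summ <- list()
  a <- (1 - cfg$coverage) / 2
  for (b in bins) {
    dates <- records$date[records$bin == b]
    n <- length(dates)
    bcfg <- cfg
    if (!is.null(cfg$seed)) bcfg$seed <- stage_seed(cfg$seed, paste0("bin", b))
    rs <- resample_bin(dates, bcfg)
    # replicate-major layout: one column per replicate on the unwrapped axis
    m <- matrix((rs$doy - origin) %% DOY_CIRCLE, nrow = n)
    if (n >= 2) {
      q <- apply(m, 2, quantile, probs = c(a, 0.5, 1 - a), names = FALSE,
                 type = 7)
      starts <- origin + q[1, ]
      meds <- origin + q[2, ]
      ends <- origin + q[3, ]
    } else {
      starts <- meds <- ends <- origin + m[1, ]
    }
    per_rep <- tibble::tibble(
      bin = b, replicate = seq_len(cfg$n_replicates),
      start = starts, end = ends, length_days = ends - starts,
      median_doy = meds)
    reps[[length(reps) + 1]] <- per_rep
    start_doy <- median(per_rep$start)
    end_doy <- median(per_rep$end)
    summ[[length(summ) + 1]] <- tibble::tibble(
      bin = b, n_records = n, start_doy = start_doy, end_doy = end_doy,
      length_days = end_doy - start_doy,
      length_months = (end_doy - start_doy) / MONTH_DAYS,
      low_confidence = n < 2)
  }
  out <- list(summary = dplyr::bind_rows(summ),
              replicates = dplyr::bind_rows(reps),
              coverage = cfg$coverage, origin = origin)
  class(out) <- "season_estimate"
  out
}

#' @export
print.season_estimate <- function(x, ...) {
  cat("<season_estimate> core ", round(100 * x$coverage), "% window, ",
      nrow(x$summary), " bin(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Linear trend of the median shark-bite date across bins
#'
#' Ordinary least squares of replicate median day-of-year on bin index
#' (one point per replicate per bin), so the slope is in days per
#' bin-step -- days per 3 years under the default tri-annual binning. The
#' total advance is `|slope| * (n_bins - 1)`.
#'
#' @param replicates A tibble with `bin` and `median_doy` columns --
#'   typically `season_by_bin(...)$replicates`, but a one-row-per-bin
#'   table of medians works identically.
#' @return A one-row tibble: `slope`, `slope_se`, `intercept`,
#'   `r_squared`, `p_value`, `total_advance_days`, `n_points`, `n_bins`.
#'   When replicate-level data are supplied (a `replicate` column with
#'   more than one replicate), `slope_se` is the bootstrap standard error
#'   -- the standard deviation of per-replicate slopes -- which, unlike
#'   the naive OLS standard error on pseudo-replicated points, reflects
#'   the resampling uncertainty of the bin medians. Otherwise it is the
#'   OLS standard error.
#' @export
median_trend <- function(replicates) {
  bins <- unique(replicates$bin)
  if (length(bins) < 2) stop("trend needs at least 2 bins", call. = FALSE)
  fit <- lm(median_doy ~ bin, data = replicates)
  sm <- summary(fit)
  slope <- unname(coef(fit)[2])
  p <- unname(sm$coefficients[2, 4])
  se <- unname(sm$coefficients[2, 2])
  if ("replicate" %in% names(replicates) &&
      length(unique(replicates$replicate)) > 1) {
    per_rep <- replicates |>
      dplyr::group_by(.data$replicate) |>
      dplyr::summarise(
        s = {
          b <- .data$bin - mean(.data$bin)
          sum(b * .data$median_doy) / sum(b^2)
        },
        .groups = "drop")
    se <- stats::sd(per_rep$s)
  }
  tibble::tibble(
    slope = slope, slope_se = se, intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared, p_value = p,
    total_advance_days = abs(slope) * (max(bins) - min(bins)),
    n_points = nrow(replicates), n_bins = length(bins))
}
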