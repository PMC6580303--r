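#' Configuration for the synthetic surveillance-data generator
#'
#' Builds the configuration object consumed by [gen_strandings()],
#' [gen_detections()] and [gen_incidents()]. The generator emulates the
#' three surveillance streams the analysis pipeline consumes: live-stranding
#' records with per-bin demographic composition and a seasonal (wrapped
#' normal) shark-bite phenology, daily shark detections and weekly seal
#' census counts with arrival/peak/departure structure, and a shark-incident
#' log containing both valid rows and distractors that the incident filter
#' must reject.
#'
#' Defaults describe the study system: seven tri-annual periods starting in
#' 1997, per-cell stranding counts taken from the shipped tri-annual
#' stranding summary ([otter_stranding_counts()]), shark-bite seasonal
#' centres advancing by 13.73 days per period from day 265, and core-80%
#' season widths growing from 60 to 240 days (about 2 to 8 months) across
#' periods.
#'
#' @param seed Master integer seed; every stochastic stage derives its own
#'   stream from it.
#' @param n_bins Number of consecutive multi-year periods.
#' @param bin_width_years Width of each period in calendar years.
#' @param start_year First calendar year of period 0.
#' @param cells Tibble with columns `bin` (0-based period index), `sex`
#'   (`"M"`/`"F"`), `maturity` (`"immature"`/`"mature"`), `cause`
#'   (`"shark"`/`"other"`) and nonnegative integer `count`.
#' @param season_center Numeric vector, length `n_bins`: day-of-year centre
#'   of the shark-bite season per period.
#' @param season_width80 Numeric vector, length `n_bins`: length in days of
#'   the central 80% window of the shark-bite season per period. Values
#'   below 1 day are raised to 1.
#' @param shark_phase List with `arrival_doy`, `peak_doy`, `departure_doy`
#'   and `n_individuals` describing the coastal detection pulse of tagged
#'   sharks.
#' @param seal_census List with `peak_doy`, `spread_days` and `peak_count`
#'   describing the weekly seal haul-out census.
#' @param incident_log List with `n_valid`, `n_distractors`, `year_range`
#'   (length-2 integer), `season_center` and `season_sd` for the
#'   human-incident log.
#' @param detection_years Length-2 integer: calendar span of the daily
#'   shark detection series.
#' @param seal_years Length-2 integer: calendar span of the weekly seal
#'   census series.
#' @param n_pups,n_geriatric_other Optional extra stranding rows (pups,
#'   and geriatric animals with non-shark causes) spread uniformly over the
#'   study span; both are excluded by [apply_stranding_exclusions()] and
#'   default to 0.
#' @return A list of class `synthetic_config`.
#' @seealso [gen_strandings()], [gen_detections()], [gen_incidents()],
#'   [write_synthetic()]
#' @export
synthetic_config <- function(seed = 1L,
                             n_bins = 7L,
                             bin_width_years = 3L,
                             start_year = 1997L,
                             cells = NULL,
                             season_center = 265 - 13.73 * (seq_len(n_bins) - 1),
                             season_width80 = seq(60, 240, length.out = n_bins),
                             shark_phase = list(arrival_doy = 213, peak_doy = 288,
                                                departure_doy = 60, n_individuals = 30),
                             seal_census = list(peak_doy = 305, spread_days = 30,
                                                peak_count = 400),
                             incident_log = list(n_valid = 75, n_distractors = 40,
                                                 year_range = c(1997L, 2018L),
                                                 season_center = 240, season_sd = 40),
                             detection_years = c(2007L, 2013L),
                             seal_years = c(1987L, 2013L),
                             n_pups = 0L,
                             n_geriatric_other = 0L) {
  if (is.null(cells)) {
    cells <- otter_stranding_counts()$cells
  }
  cfg <- list(
    seed = as.integer(seed), n_bins = as.integer(n_bins),
    bin_width_years = as.integer(bin_width_years),
    start_year = as.integer(start_year),
    cells = tibble::as_tibble(cells),
    season_center = ((season_center - 1) %% DOY_CIRCLE) + 1,
    season_width80 = pmax(season_width80, 1),
    shark_phase = shark_phase, seal_census = seal_census,
    incident_log = incident_log,
    detection_years = as.integer(detection_years),
    seal_years = as.integer(seal_years),
    n_pups = as.integer(n_pups),
    n_geriatric_other = as.integer(n_geriatric_other)
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  cells <- cfg$cells
  need <- c("bin", "sex", "maturity", "cause", "count")
  if (!all(need %in% names(cells))) {
    stop("`cells` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(cells$count < 0)) stop("cell counts must be nonnegative", call. = FALSE)
  if (any(cells$bin < 0 | cells$bin >= cfg$n_bins)) {
    stop("cell bins must lie in [0, n_bins)", call. = FALSE)
  }
  if (length(cfg$season_center) != cfg$n_bins ||
      length(cfg$season_width80) != cfg$n_bins) {
    stop("season_center and season_width80 must have one value per bin",
         call. = FALSE)
  }
  if (any(cfg$season_width80 <= 0)) stop("season_width80 must be > 0", call. = FALSE)
  ph <- cfg$shark_phase
  if (any(c(ph$arrival_doy, ph$peak_doy, ph$departure_doy) < 1) ||
      any(c(ph$arrival_doy, ph$peak_doy, ph$departure_doy) > DOY_CIRCLE)) {
    stop("shark phase days must be valid days-of-year", call. = FALSE)
  }
  invisible(cfg)
}

## z such that the central 80% of a normal spans 2*z standard deviations
Z80 <- qnorm(0.9)

#' Generate synthetic live-stranding records
#'
#' Emits exactly the configured number of records per (period, sex,
#' maturity, cause) cell. Shark-attributed dates are drawn from a wrapped
#' normal on the 366-day circle with the period's seasonal centre and a
#' standard deviation calibrated so the central 80% of draws spans the
#' period's `season_width80`; other-cause dates are uniform over the
#' period's calendar span (the no-seasonality null). Record years are
#' uniform within the period.
#'
#' @param cfg A [synthetic_config()].
#' @return A tibble with columns `date`, `sex`, `age_class`, `cause`,
#'   `alive_at_recovery`, plus a `ground_truth` attribute (see
#'   [ground_truth()]).
#' @export
gen_strandings <- function(cfg) {
  validate_synthetic_config(cfg)
  withr::with_seed(stage_seed(cfg$seed, "strandings"), {
    cells <- dplyr::filter(cfg$cells, .data$count > 0)
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      cell <- cells[i, ]
      n <- cell$count
      y0 <- cfg$start_year + cell$bin * cfg$bin_width_years
      years <- sample(y0:(y0 + cfg$bin_width_years - 1), n, replace = TRUE)
      if (cell$cause == "shark") {
        ctr <- cfg$season_center[cell$bin + 1]
        sd <- cfg$season_width80[cell$bin + 1] / (2 * Z80)
        d <- ((round(rnorm(n, ctr, sd)) - 1) %% DOY_CIRCLE) + 1
        dates <- doy_date(d, years)
      } else {
        lo <- as.numeric(as.Date(paste0(y0, "-01-01")))
        hi <- as.numeric(as.Date(paste0(y0 + cfg$bin_width_years - 1, "-12-31")))
        dates <- as.Date(round(runif(n, lo, hi)), origin = "1970-01-01")
      }
      tibble::tibble(date = dates, sex = cell$sex, age_class = cell$maturity,
                     cause = cell$cause)
    })
    out <- dplyr::bind_rows(rows)
    out <- dplyr::bind_rows(out, gen_excluded_strata(cfg))
    out$alive_at_recovery <- TRUE
    out <- dplyr::arrange(out, .data$date)
  })
  attr(out, "ground_truth") <- ground_truth(cfg)
  out
}

## pup and geriatric/other rows, uniform over the whole study span; these
## exist only so downstream exclusion rules have something to remove
gen_excluded_strata <- function(cfg) {
  n <- cfg$n_pups + cfg$n_geriatric_other
  if (n == 0) return(NULL)
  lo <- as.numeric(as.Date(paste0(cfg$start_year, "-01-01")))
  hi <- as.numeric(as.Date(paste0(
    cfg$start_year + cfg$n_bins * cfg$bin_width_years - 1, "-12-31")))
  tibble::tibble(
    date = as.Date(round(runif(n, lo, hi)), origin = "1970-01-01"),
    sex = sample(c("M", "F"), n, replace = TRUE),
    age_class = rep(c("pup", "geriatric"), c(cfg$n_pups, cfg$n_geriatric_other)),
    cause = rep(c("other", "other"), c(cfg$n_pups, cfg$n_geriatric_other))
  )
}

#' Ground truth of a synthetic configuration
#'
#' The generator's known structure, used by recovery tests: per-period
#' seasonal centre and core-80% width, per-period shark counts, the true
#' linear trend of the seasonal centre (days per period), and the true male
#' proportion in the mature and immature shark/other strata.
#'
#' @param cfg A [synthetic_config()].
#' @return A named list.
#' @export
ground_truth <- function(cfg) {
  cells <- cfg$cells
  bias <- function(maturity, cause) {
    sub <- dplyr::filter(cells, .data$maturity == .env$maturity,
                         .data$cause == .env$cause)
    m <- sum(sub$count[sub$sex == "M"])
    tot <- sum(sub$count)
    if (tot == 0) NA_real_ else m / tot
  }
  fit <- lm(cfg$season_center ~ seq(0, cfg$n_bins - 1))
  list(
    season_center = cfg$season_center,
    season_width80 = cfg$season_width80,
    n_shark_per_bin = vapply(seq_len(cfg$n_bins) - 1, function(b) {
      sum(cells$count[cells$bin == b & cells$cause == "shark"])
    }, numeric(1)),
    trend_slope_days_per_bin = unname(coef(fit)[2]),
    male_bias = c(mature_shark = bias("mature", "shark"),
                  mature_other = bias("mature", "other"),
                  immature_shark = bias("immature", "shark"),
                  immature_other = bias("immature", "other"))
  )
}

#' Relative intensity of the shark coastal detection pulse
#'
#' Piecewise-linear circular ramp: 0 before `arrival`, rising to 1 at
#' `peak`, falling back to 0 at `departure`, wrapping across the new year
#' when the phase straddles it.
#'
#' @param d Day-of-year vector.
#' @param arrival,peak,departure Phase days-of-year.
#' @return Numeric in `[0, 1]`.
#' @export
detection_intensity <- function(d, arrival, peak, departure) {
  up <- (peak - arrival) %% DOY_CIRCLE
  total <- (departure - arrival) %% DOY_CIRCLE
  pos <- (d - arrival) %% DOY_CIRCLE
  out <- numeric(length(d))
  rising <- pos <= up & up > 0
  falling <- pos > up & pos <= total
  out[rising] <- pos[rising] / up
  out[falling] <- 1 - (pos[falling] - up) / (total - up)
  out[pos == 0 & up == 0] <- 1
  out
}

#' Generate synthetic detection series
#'
#' Produces the pair of monitored-abundance series the phenology module
#' consumes: a daily count of tagged sharks detected across coastal
#' monitoring sites (Poisson around a piecewise arrival/peak/departure
#' ramp) and a weekly seal census count (Poisson around a Gaussian bump on
#' the day-of-year circle).
#'
#' @param cfg A [synthetic_config()].
#' @return A list with tibbles `shark` (daily) and `seal` (weekly), each
#'   with columns `species`, `cadence`, `date`, `count`.
#' @export
gen_detections <- function(cfg) {
  validate_synthetic_config(cfg)
  withr::with_seed(stage_seed(cfg$seed, "detections"), {
    ph <- cfg$shark_phase
    days <- seq(as.Date(paste0(cfg$detection_years[1], "-01-01")),
                as.Date(paste0(cfg$detection_years[2], "-12-31")), by = "day")
    lam <- ph$n_individuals *
      detection_intensity(doy(days), ph$arrival_doy, ph$peak_doy, ph$departure_doy)
    shark <- tibble::tibble(species = "shark", cadence = "daily",
                            date = days, count = rpois(length(days), lam))
    sc <- cfg$seal_census
    weeks <- seq(as.Date(paste0(cfg$seal_years[1], "-01-04")),
                 as.Date(paste0(cfg$seal_years[2], "-12-31")), by = "7 days")
    lam_s <- sc$peak_count *
      exp(-0.5 * (circ_diff(sc$peak_doy, doy(weeks)) / sc$spread_days)^2)
    seal <- tibble::tibble(species = "seal", cadence = "weekly",
                           date = weeks, count = rpois(length(weeks), lam_s))
    list(shark = shark, seal = seal)
  })
}

#' Generate a synthetic shark-incident log
#'
#' Emits `n_valid` rows that satisfy every inclusion criterion used for
#' human shark-bite incidents (white shark, unprovoked, injurious,
#' California, within the year range) plus `n_distractors` rows that each
#' violate exactly one criterion, cycling through the five violation types.
#' The violated criterion is recorded per row so filter tests can assert
#' exact rejection.
#'
#' @param cfg A [synthetic_config()].
#' @return A tibble with columns `date`, `species_label`, `provoked`,
#'   `injurious`, `region`, `fatal`, `violation`.
#' @export
gen_incidents <- function(cfg) {
  validate_synthetic_config(cfg)
  il <- cfg$incident_log
  withr::with_seed(stage_seed(cfg$seed, "incidents"), {
    draw <- function(n, years) {
      yr <- sample(years[1]:years[2], n, replace = TRUE)
      d <- ((round(rnorm(n, il$season_center, il$season_sd)) - 1) %% DOY_CIRCLE) + 1
      doy_date(d, yr)
    }
    n_v <- il$n_valid
    valid <- tibble::tibble(
      date = draw(n_v, il$year_range), species_label = "white shark",
      provoked = FALSE, injurious = TRUE, region = "California",
      fatal = if (n_v > 0) runif(n_v) < 0.1 else logical(0),
      violation = "none"
    )
    n_d <- il$n_distractors
    if (n_d > 0) {
      kinds <- rep_len(c("species", "provoked", "injurious", "region", "year"), n_d)
      dis <- tibble::tibble(
        date = draw(n_d, il$year_range), species_label = "white shark",
        provoked = FALSE, injurious = TRUE, region = "California",
        fatal = runif(n_d) < 0.1, violation = kinds
      )
      dis$species_label[kinds == "species"] <- "tiger shark"
      dis$provoked[kinds == "provoked"] <- TRUE
      dis$injurious[kinds == "injurious"] <- FALSE
      dis$region[kinds == "region"] <- "Florida"
      n_y <- sum(kinds == "year")
      if (n_y > 0) {
        dis$date[kinds == "year"] <- draw(
          n_y, c(il$year_range[1] - 5L, il$year_range[1] - 1L))
      }
      valid <- dplyr::bind_rows(valid, dis)
    }
    dplyr::arrange(valid, .data$date)
  })
}

#' Write a synthetic dataset bundle to disk
#'
#' Writes the three surveillance streams as headered CSV with ISO-8601
#' dates, plus a key-value ground-truth sidecar (`ground_truth.txt`) so
#' recovery tests can read back the generator's known structure.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synthetic <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  strandings <- gen_strandings(cfg)
  detections <- gen_detections(cfg)
  incidents <- gen_incidents(cfg)
  paths <- c(
    strandings = file.path(dir, "strandings.csv"),
    detections_shark = file.path(dir, "detections_shark.csv"),
    detections_seal = file.path(dir, "detections_seal.csv"),
    incidents = file.path(dir, "incidents.csv"),
    ground_truth = file.path(dir, "ground_truth.txt")
  )
  readr::write_csv(strandings, paths[["strandings"]])
  readr::write_csv(detections$shark, paths[["detections_shark"]])
  readr::write_csv(detections$seal, paths[["detections_seal"]])
  readr::write_csv(incidents, paths[["incidents"]])
  gt <- ground_truth(cfg)
  lines <- c(
    paste0("season_center: ", paste(gt$season_center, collapse = ",")),
    paste0("season_width80: ", paste(gt$season_width80, collapse = ",")),
    paste0("n_shark_per_bin: ", paste(gt$n_shark_per_bin, collapse = ",")),
    paste0("trend_slope_days_per_bin: ", gt$trend_slope_days_per_bin),
    paste0("male_bias_", names(gt$male_bias), ": ", gt$male_bias)
  )
  writeLines(lines, paths[["ground_truth"]])
  invisible(paths)
}
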