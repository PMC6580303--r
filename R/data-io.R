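#' Tri-annual summary counts of live-stranded southern sea otters, 1997-2017
#'
#' The published tri-annual summary of the central-California live-stranding
#' record: per-period counts of live-stranded sea otters by sex, maturity
#' class, and whether shark trauma was attributed as the cause of stranding,
#' together with the per-period printed totals of shark- and
#' non-shark-attributed strandings. Shipped as plain CSV under
#' `inst/extdata/`.
#'
#' In four periods the sex-by-maturity shark cells do not sum to the printed
#' shark total; [counts_consistency()] surfaces these discrepancies rather
#' than reconciling them silently. With `reconciled = TRUE` the shark cells
#' of each period are proportionally rescaled (largest-remainder rounding)
#' so they sum to the printed totals, which is the configuration used when
#' the synthetic generator is asked to mimic the printed per-period totals.
#'
#' @param reconciled Logical; rescale shark cells to the printed per-period
#'   totals (default `FALSE`: cells exactly as printed).
#' @return A list with tibbles `cells` (`period`, `bin`, `sex`, `maturity`,
#'   `cause`, `count`) and `totals` (`period`, `bin`, `shark_total`,
#'   `nonshark_total`).
#' @export
otter_stranding_counts <- function(reconciled = FALSE) {
  cells <- readr::read_csv(
    system.file("extdata", "otter_stranding_cells.csv", package = "otterphen"),
    col_types = readr::cols(
      period = "c", bin = "i", sex = "c", maturity = "c", cause = "c",
      count = "i"))
  totals <- readr::read_csv(
    system.file("extdata", "otter_stranding_totals.csv", package = "otterphen"),
    col_types = readr::cols(period = "c", bin = "i", shark_total = "i",
                            nonshark_total = "i"))
  if (reconciled) {
    cells <- dplyr::bind_rows(lapply(split(cells, cells$bin), function(cb) {
      tgt <- totals$shark_total[totals$bin == cb$bin[1]]
      shark <- cb$cause == "shark"
      cb$count[shark] <- round_to_total(cb$count[shark], tgt)
      cb
    }))
    cells <- dplyr::arrange(cells, .data$bin, dplyr::desc(.data$sex))
  }
  list(cells = cells, totals = totals)
}

## largest-remainder rounding of x rescaled to sum to `total`
round_to_total <- function(x, total) {
  if (sum(x) == 0) {
    out <- integer(length(x))
    out[seq_len(total)] <- 1L  # degenerate: spread evenly
    return(out)
  }
  quota <- x * total / sum(x)
  out <- floor(quota)
  rem <- total - sum(out)
  if (rem > 0) {
    idx <- order(quota - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1
  }
  as.integer(out)
}

#' Check cell sums against printed per-period totals
#'
#' @param counts A list as returned by [otter_stranding_counts()], or any
#'   pair of `cells`/`totals` tibbles in the same layout.
#' @return A tibble with one row per period and cause, giving the cell sum,
#'   the printed total, and a `consistent` flag.
#' @export
counts_consistency <- function(counts = otter_stranding_counts()) {
  sums <- counts$cells |>
    dplyr::group_by(.data$period, .data$bin, .data$cause) |>
    dplyr::summarise(cell_sum = sum(.data$count), .groups = "drop")
  printed <- counts$totals |>
    tidyr::pivot_longer(c("shark_total", "nonshark_total"),
                        names_to = "cause", values_to = "printed_total") |>
    dplyr::mutate(cause = ifelse(.data$cause == "shark_total", "shark", "other"))
  dplyr::left_join(sums, printed, by = c("period", "bin", "cause")) |>
    dplyr::mutate(consistent = .data$cell_sum == .data$printed_total) |>
    dplyr::arrange(.data$bin, .data$cause)
}

#' Expand aggregated counts into individual pseudo-records
#'
#' Turns a cell-count table into one row per animal, which is the form the
#' demographic bootstrap resamples. Inverse (up to row order) of the cell
#' aggregation in [aggregate_counts()].
#'
#' @param cells Tibble with `sex`, `maturity`, `cause`, `count` and
#'   optionally `bin`/`period` columns.
#' @return A tibble with one row per counted animal.
#' @export
counts_to_records <- function(cells) {
  keep <- setdiff(names(cells), "count")
  out <- cells[rep(seq_len(nrow(cells)), cells$count), keep]
  tibble::as_tibble(out)
}

stranding_sex_levels <- c("M", "F", "unknown")
stranding_age_levels <- c("pup", "immature", "mature", "geriatric")
stranding_cause_levels <- c("shark", "other")

#' Read and validate live-stranding records
#'
#' Reads a headered CSV of stranding records, optionally renaming columns
#' through `col_map`, and validates every row: dates must parse (ISO-8601),
#' `sex` must be one of `M`, `F`, `unknown`, `age_class` one of `pup`,
#' `immature`, `mature`, `geriatric`, and `cause` one of `shark`, `other`.
#' Invalid rows are rejected; rows with `sex = "unknown"` are retained but
#' flagged. The row-indexed validation report is attached as the
#' `validation_report` attribute (see [validation_report()]).
#'
#' @param path Path to a CSV file with columns `date`, `sex`, `age_class`,
#'   `cause` and optionally `alive_at_recovery`.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   `c(date = "StrandDate", sex = "Sex")`.
#' @return A tibble of validated stranding records.
#' @export
read_strandings <- function(path, col_map = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  raw <- apply_col_map(raw, col_map)
  need <- c("date", "sex", "age_class", "cause")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("stranding file is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  report <- list()
  date <- suppressWarnings(as.Date(raw$date, format = "%Y-%m-%d"))
  bad_date <- which(is.na(date))
  for (i in bad_date) {
    report[[length(report) + 1]] <- c(i, "date", "unparseable date", "rejected")
  }
  bad_sex <- which(!raw$sex %in% stranding_sex_levels)
  for (i in bad_sex) {
    report[[length(report) + 1]] <-
      c(i, "sex", paste0("invalid sex '", raw$sex[i], "'"), "rejected")
  }
  unk_sex <- which(raw$sex == "unknown")
  for (i in unk_sex) {
    report[[length(report) + 1]] <- c(i, "sex", "unknown sex", "flagged")
  }
  bad_age <- which(!raw$age_class %in% stranding_age_levels)
  for (i in bad_age) {
    report[[length(report) + 1]] <-
      c(i, "age_class", paste0("invalid age_class '", raw$age_class[i], "'"),
        "rejected")
  }
  bad_cause <- which(!raw$cause %in% stranding_cause_levels)
  for (i in bad_cause) {
    report[[length(report) + 1]] <-
      c(i, "cause", paste0("invalid cause '", raw$cause[i], "'"), "rejected")
  }
  report <- validation_tibble(report)
  drop <- unique(report$row[report$action == "rejected"])
  out <- tibble::tibble(
    date = date, sex = raw$sex, age_class = raw$age_class, cause = raw$cause,
    alive_at_recovery = if ("alive_at_recovery" %in% names(raw)) {
      as.logical(raw$alive_at_recovery)
    } else TRUE
  )
  if (length(drop) > 0) out <- out[-drop, ]
  attr(out, "validation_report") <- report
  out
}

apply_col_map <- function(raw, col_map) {
  if (is.null(col_map)) return(raw)
  for (canon in names(col_map)) {
    if (col_map[[canon]] %in% names(raw)) {
      names(raw)[names(raw) == col_map[[canon]]] <- canon
    }
  }
  raw
}

validation_tibble <- function(report) {
  if (length(report) == 0) {
    return(tibble::tibble(row = integer(), field = character(),
                          reason = character(), action = character()))
  }
  m <- do.call(rbind, report)
  tibble::tibble(row = as.integer(m[, 1]), field = m[, 2], reason = m[, 3],
                 action = m[, 4])
}

#' @rdname read_strandings
#' @param x A tibble returned by one of the readers.
#' @export
validation_report <- function(x) {
  rep <- attr(x, "validation_report")
  if (is.null(rep)) validation_tibble(list()) else rep
}

#' Read a shark-incident log
#'
#' @param path CSV with columns `date`, `species_label`, `provoked`,
#'   `injurious`, `region` and optionally `fatal`.
#' @inheritParams read_strandings
#' @return A tibble of incident records; rows with unparseable dates are
#'   rejected and reported via [validation_report()].
#' @export
read_incidents <- function(path, col_map = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  raw <- apply_col_map(raw, col_map)
  need <- c("date", "species_label", "provoked", "injurious", "region")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("incident file is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  date <- suppressWarnings(as.Date(raw$date, format = "%Y-%m-%d"))
  report <- list()
  for (i in which(is.na(date))) {
    report[[length(report) + 1]] <- c(i, "date", "unparseable date", "rejected")
  }
  report <- validation_tibble(report)
  out <- tibble::tibble(
    date = date, species_label = raw$species_label,
    provoked = as.logical(raw$provoked), injurious = as.logical(raw$injurious),
    region = raw$region,
    fatal = if ("fatal" %in% names(raw)) as.logical(raw$fatal) else NA
  )
  drop <- unique(report$row[report$action == "rejected"])
  if (length(drop) > 0) out <- out[-drop, ]
  attr(out, "validation_report") <- report
  out
}

#' Read a detection (monitored-abundance) series
#'
#' @param path CSV with columns `date`, `count` and optionally `species`,
#'   `cadence`.
#' @inheritParams read_strandings
#' @return A tibble sorted by date. Negative counts or duplicated dates are
#'   an error (the series must be strictly increasing in date).
#' @export
read_detections <- function(path, col_map = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  raw <- apply_col_map(raw, col_map)
  if (!all(c("date", "count") %in% names(raw))) {
    stop("detection file needs `date` and `count` columns", call. = FALSE)
  }
  out <- tibble::tibble(
    species = if ("species" %in% names(raw)) raw$species else NA_character_,
    cadence = if ("cadence" %in% names(raw)) raw$cadence else NA_character_,
    date = as.Date(raw$date), count = as.numeric(raw$count)
  )
  if (anyNA(out$date)) stop("detection series has unparseable dates", call. = FALSE)
  if (any(out$count < 0)) stop("detection counts must be nonnegative", call. = FALSE)
  out <- dplyr::arrange(out, .data$date)
  if (anyDuplicated(out$date)) {
    stop("detection series dates must be strictly increasing", call. = FALSE)
  }
  out
}

#' Filter a shark-incident log to the analysis set
#'
#' Retains incidents that satisfy all criteria simultaneously: the given
#' species label, unprovoked, injurious, the given region, and a date
#' within the year range. Row order is preserved and the operation is
#' idempotent.
#'
#' @param records Incident tibble ([read_incidents()] or [gen_incidents()]).
#' @param species_label,region Character criteria (exact match).
#' @param provoked,injurious Logical criteria.
#' @param year_range Length-2 integer vector of inclusive calendar years.
#' @return The retained subset, same columns and order.
#' @export
filter_incidents <- function(records, species_label = "white shark",
                             provoked = FALSE, injurious = TRUE,
                             region = "California",
                             year_range = c(1997L, 2018L)) {
  stopifnot(nzchar(species_label), nzchar(region), length(year_range) == 2)
  yr <- as.integer(format(records$date, "%Y"))
  keep <- records$species_label == species_label &
    records$provoked == provoked &
    records$injurious == injurious &
    records$region == region &
    yr >= year_range[1] & yr <= year_range[2]
  records[which(keep), ]
}

#' Apply demographic exclusion rules to stranding records
#'
#' Removes strata whose stranding circumstances are unique to their
#' demographic: all pups (< 6 months), and geriatric animals (> 10 years)
#' whose stranding was not attributed to shark trauma. Shark-bitten
#' geriatrics are retained; all other records pass through unchanged.
#'
#' @param records Stranding tibble.
#' @return The retained subset; the number removed per rule is attached as
#'   the `exclusions` attribute.
#' @export
apply_stranding_exclusions <- function(records) {
  pup <- records$age_class == "pup"
  ger_nonshark <- records$age_class == "geriatric" & records$cause != "shark"
  out <- records[!(pup | ger_nonshark), ]
  attr(out, "exclusions") <- c(pups = sum(pup),
                               geriatric_nonshark = sum(ger_nonshark))
  out
}

#' Assign stranding records to multi-year periods
#'
#' A record from calendar year `y` is assigned to bin
#' `floor((y - start_year) / width_years)` (0-based). Records earlier than
#' `start_year` are excluded with a warning, never silently.
#'
#' @param records Stranding tibble with a `date` column.
#' @param start_year First year of bin 0.
#' @param width_years Bin width in calendar years (>= 1).
#' @return `records` with added integer columns `year` and `bin`; excluded
#'   early records are reported in the `excluded_early` attribute.
#' @export
assign_bins <- function(records, start_year = 1997L, width_years = 3L) {
  stopifnot(width_years >= 1)
  year <- as.integer(format(records$date, "%Y"))
  early <- which(year < start_year)
  if (length(early) > 0) {
    warning(length(early), " record(s) before ", start_year, " excluded",
            call. = FALSE)
  }
  out <- records
  out$year <- year
  out$bin <- (year - start_year) %/% as.integer(width_years)
  keep <- out[out$year >= start_year, ]
  attr(keep, "excluded_early") <- records[early, ]
  keep
}

#' Aggregate binned stranding records into period summary counts
#'
#' Produces the per-period cell counts (sex by maturity by cause) and
#' per-period totals of shark- and non-shark-attributed strandings. Two
#' proportion columns are emitted, clearly labelled: `quotient` is the
#' ratio shark_total / nonshark_total (the convention of the published
#' summary table) and `prop_shark` is shark_total / (shark_total +
#' nonshark_total). In a period with no non-shark strandings the quotient
#' is reported as `NA`, not an error.
#'
#' @param binned Stranding tibble with `bin`, `sex`, `age_class`, `cause`
#'   columns ([assign_bins()] output, post-exclusion).
#' @return A list with tibbles `cells` and `totals` plus the scalar
#'   `grand_total`.
#' @export
aggregate_counts <- function(binned) {
  cells <- binned |>
    dplyr::count(.data$bin, .data$sex, maturity = .data$age_class,
                 .data$cause, name = "count") |>
    dplyr::arrange(.data$bin)
  totals <- cells |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      shark_total = sum(.data$count[.data$cause == "shark"]),
      nonshark_total = sum(.data$count[.data$cause != "shark"]),
      .groups = "drop") |>
    dplyr::mutate(
      quotient = ifelse(.data$nonshark_total > 0,
                        .data$shark_total / .data$nonshark_total, NA_real_),
      prop_shark = .data$shark_total /
        (.data$shark_total + .data$nonshark_total))
  list(cells = cells, totals = totals, grand_total = nrow(binned))
}
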