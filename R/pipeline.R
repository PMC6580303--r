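#' Configuration for an end-to-end pipeline run
#'
#' Exactly one data source must be set: either `synthetic` (a
#' [synthetic_config()], or `TRUE` for the default study-system
#' configuration) or `input`, a named list of file paths (`strandings`
#' required; `detections_shark`, `detections_seal`, `incidents` optional).
#' The master `seed` derives a substream for every stochastic stage by a
#' stage-name hash, so adding a stage never shifts the streams of the
#' others.
#'
#' @param synthetic A [synthetic_config()], `TRUE`, or `NULL`.
#' @param input Named list of input CSV paths, or `NULL`.
#' @param col_map Optional column-name mapping passed to the readers.
#' @param start_year,bin_width_years Bin scheme for the stranding record.
#' @param bandwidth Phenology kernel bandwidth in days, or `"auto"`.
#' @param bootstrap A [bootstrap_config()] (seed filled from `seed` if
#'   unset).
#' @param perturbation A [perturbation_config()] (seed filled from `seed`
#'   if unset).
#' @param incident_criteria Named list of arguments for
#'   [filter_incidents()].
#' @param out_dir Output directory for the result bundle, or `NULL` to
#'   return results without writing.
#' @param save_replicates Write the replicate-level season table (large)
#'   alongside the summaries.
#' @param seed Master integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, input = NULL, col_map = NULL,
                       start_year = 1997L, bin_width_years = 3L,
                       bandwidth = "auto",
                       bootstrap = bootstrap_config(),
                       perturbation = perturbation_config(),
                       incident_criteria = list(),
                       out_dir = NULL, save_replicates = FALSE, seed = 1L) {
  if (is.null(synthetic) && is.null(input)) {
    stop("configuration error: set exactly one of `synthetic` or `input` ",
         "(neither is set)", call. = FALSE)
  }
  if (!is.null(synthetic) && !is.null(input)) {
    stop("configuration error: set exactly one of `synthetic` or `input` ",
         "(both are set)", call. = FALSE)
  }
  if (isTRUE(synthetic)) {
    synthetic <- synthetic_config(seed = stage_seed(seed, "synthetic"))
  }
  if (is.null(bootstrap$seed)) bootstrap$seed <- stage_seed(seed, "demographics")
  if (is.null(perturbation$seed)) perturbation$seed <- stage_seed(seed, "season")
  structure(list(synthetic = synthetic, input = input, col_map = col_map,
                 start_year = as.integer(start_year),
                 bin_width_years = as.integer(bin_width_years),
                 bandwidth = bandwidth, bootstrap = bootstrap,
                 perturbation = perturbation,
                 incident_criteria = incident_criteria,
                 out_dir = out_dir, save_replicates = save_replicates,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised top-level keys mirror the [run_config()] arguments; the
#' `bootstrap` and `perturbation` keys take nested maps of the respective
#' config arguments, and `synthetic: true` selects the default synthetic
#' study system.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides passed on to [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  args <- list(...)
  for (key in c("synthetic", "input", "col_map", "start_year",
                "bin_width_years", "bandwidth", "incident_criteria",
                "out_dir", "save_replicates", "seed")) {
    if (!is.null(y[[key]]) && is.null(args[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$bootstrap)) {
    args$bootstrap <- do.call(bootstrap_config, y$bootstrap)
  }
  if (!is.null(y$perturbation)) {
    args$perturbation <- do.call(perturbation_config, y$perturbation)
  }
  do.call(run_config, args)
}

#' Run the full stranding-phenology analysis pipeline
#'
#' Executes the complete sequence: acquire data (generate or read), apply
#' demographic exclusions and validation, assign tri-annual bins,
#' aggregate period counts, estimate seasonal densities for every stream,
#' run the demographic test battery and bootstrap male-bias summaries,
#' estimate per-bin core seasonal windows, and fit the median-date trend.
#' If `out_dir` is set, writes all tables as CSV, a machine-readable
#' `summary.json`, and a `run_log.txt` recording seeds and the analysis
#' conventions in effect.
#'
#' @param cfg A [run_config()].
#' @return A result bundle (list) with elements `counts`, `phenology`,
#'   `demographics`, `season`, `trend`, `validation`, `paths` (when
#'   written).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log <- character()
  say <- function(...) log <<- c(log, paste0(...))
  say("otterphen run, master seed ", cfg$seed)

  ## --- acquire -------------------------------------------------------
  if (!is.null(cfg$synthetic)) {
    say("stage data: synthetic generator, seed ", cfg$synthetic$seed)
    strandings <- gen_strandings(cfg$synthetic)
    detections <- gen_detections(cfg$synthetic)
    incidents <- gen_incidents(cfg$synthetic)
  } else {
    say("stage data: reading input files")
    if (is.null(cfg$input$strandings)) {
      stop("pipeline stage data: `input$strandings` path is required",
           call. = FALSE)
    }
    strandings <- read_strandings(cfg$input$strandings, cfg$col_map)
    detections <- list(
      shark = if (!is.null(cfg$input$detections_shark)) {
        read_detections(cfg$input$detections_shark, cfg$col_map)
      },
      seal = if (!is.null(cfg$input$detections_seal)) {
        read_detections(cfg$input$detections_seal, cfg$col_map)
      })
    incidents <- if (!is.null(cfg$input$incidents)) {
      read_incidents(cfg$input$incidents, cfg$col_map)
    }
  }
  validation <- validation_report(strandings)

  ## --- exclusions and bins ------------------------------------------
  kept <- apply_stranding_exclusions(strandings)
  say("stage exclusions: removed ",
      paste(names(attr(kept, "exclusions")), attr(kept, "exclusions"),
            sep = "=", collapse = ", "))
  sexed <- kept[kept$sex %in% c("M", "F"), ]
  n_unknown <- nrow(kept) - nrow(sexed)
  if (n_unknown > 0) {
    say("stage exclusions: ", n_unknown,
        " record(s) with unknown sex kept in totals, dropped from ",
        "sex-stratified analyses")
  }
  binned <- assign_bins(sexed, cfg$start_year, cfg$bin_width_years)
  counts <- aggregate_counts(binned)

  ## --- phenology -----------------------------------------------------
  say("stage phenology: bandwidth = ", paste(cfg$bandwidth, collapse = ""))
  phen <- list()
  shark_strand <- binned[binned$cause == "shark", ]
  phen$otter_bite <- estimate_density(doy(shark_strand$date),
                                      bandwidth = cfg$bandwidth)
  if (!is.null(detections$shark)) {
    phen$shark_detections <- relative_density(detections$shark,
                                              bandwidth = cfg$bandwidth)
  }
  if (!is.null(detections$seal)) {
    phen$seal_census <- relative_density(detections$seal,
                                         bandwidth = cfg$bandwidth)
  }
  if (!is.null(incidents)) {
    inc_kept <- do.call(filter_incidents, c(list(incidents),
                                            cfg$incident_criteria))
    say("stage phenology: incident filter retained ", nrow(inc_kept), " of ",
        nrow(incidents), " rows")
    if (nrow(inc_kept) >= 2) {
      phen$human_incidents <- estimate_density(doy(inc_kept$date),
                                               bandwidth = cfg$bandwidth)
    }
  } else inc_kept <- NULL
  peaks <- vapply(phen, peak_doy, numeric(1))
  lags <- if (!is.null(phen$shark_detections)) {
    vapply(setdiff(names(phen), "shark_detections"), function(nm) {
      phenology_lag(phen[[nm]], phen$shark_detections, "peak")
    }, numeric(1))
  } else numeric(0)

  ## --- demographics --------------------------------------------------
  say("stage demographics: Yates correction ON for 2x2 tables; ",
      "no multiple-testing correction (raw p-values)")
  tests <- list()
  add_test <- function(name, tab) {
    res <- tryCatch(chi_squared(tab), error = function(e) NULL)
    if (!is.null(res)) tests[[name]] <<- dplyr::mutate(res, comparison = name)
  }
  add_test("sex_x_cause",
           build_contingency(binned, "sex", "cause"))
  for (s in intersect(c("M", "F"), unique(binned$sex))) {
    tab <- tryCatch(build_contingency(binned, "age_class", "cause",
                                      strata = list(sex = s)),
                    error = function(e) NULL)
    if (!is.null(tab)) add_test(paste0("maturity_x_cause_", s), tab)
  }
  tests <- dplyr::bind_rows(tests)

  strata <- list(mature_shark = c("mature", "shark"),
                 mature_other = c("mature", "other"),
                 immature_shark = c("immature", "shark"),
                 immature_other = c("immature", "other"))
  bias <- dplyr::bind_rows(lapply(names(strata), function(nm) {
    sub <- binned[binned$age_class == strata[[nm]][1] &
                    binned$cause == strata[[nm]][2], ]
    if (nrow(sub) == 0) return(NULL)
    dplyr::bind_rows(
      bootstrap_bias(sub, cfg$bootstrap, grouping = "per_bin", label = nm),
      bootstrap_bias(sub, cfg$bootstrap, grouping = "pooled", label = nm))
  }))
  say("stage demographics: bootstrap n_replicates = ",
      cfg$bootstrap$n_replicates)

  ## --- season expansion ----------------------------------------------
  say("stage season: sd_rule = ", cfg$perturbation$sd_rule,
      ", sd_floor = ", cfg$perturbation$sd_floor,
      " d, truncation halfwidth = ", cfg$perturbation$truncation_halfwidth,
      " d, coverage = ", cfg$perturbation$coverage)
  season <- season_by_bin(shark_strand, cfg$perturbation)
  trend <- median_trend(season$replicates)
  say("stage season: trend slope = ", signif(trend$slope, 5),
      " days per bin, R^2 = ", signif(trend$r_squared, 4))

  bundle <- list(
    counts = counts,
    phenology = list(densities = phen, peaks = peaks, lags = lags),
    demographics = list(tests = tests, bias = bias),
    season = season, trend = trend,
    incidents_retained = if (is.null(inc_kept)) NA_integer_ else nrow(inc_kept),
    validation = validation, log = log)
  if (!is.null(cfg$out_dir)) {
    bundle$paths <- write_bundle(bundle, cfg)
  }
  invisible(bundle)
}

## serialise the result bundle: delimited tables + one JSON summary + log
write_bundle <- function(bundle, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  paths <- c(cells = p("counts_cells.csv"), totals = p("counts_totals.csv"),
             tests = p("demographic_tests.csv"), bias = p("bias_summary.csv"),
             season = p("season_summary.csv"), trend = p("trend.csv"),
             summary = p("summary.json"), log = p("run_log.txt"))
  readr::write_csv(bundle$counts$cells, paths[["cells"]])
  readr::write_csv(bundle$counts$totals, paths[["totals"]])
  readr::write_csv(bundle$demographics$tests, paths[["tests"]])
  readr::write_csv(bundle$demographics$bias, paths[["bias"]])
  readr::write_csv(bundle$season$summary, paths[["season"]])
  readr::write_csv(bundle$trend, paths[["trend"]])
  for (nm in names(bundle$phenology$densities)) {
    paths[[paste0("density_", nm)]] <- p(paste0("density_", nm, ".csv"))
    write_phenology(bundle$phenology$densities[[nm]],
                    paths[[paste0("density_", nm)]])
  }
  if (isTRUE(cfg$save_replicates)) {
    paths[["season_replicates"]] <- p("season_replicates.csv")
    readr::write_csv(bundle$season$replicates, paths[["season_replicates"]])
  }
  summary <- list(
    seed = cfg$seed,
    grand_total = bundle$counts$grand_total,
    quotients = round(bundle$counts$totals$quotient, 2),
    peaks = as.list(bundle$phenology$peaks),
    lags = as.list(bundle$phenology$lags),
    tests = stats::setNames(as.list(round(bundle$demographics$tests$value, 2)),
                            bundle$demographics$tests$comparison),
    male_bias = lapply(split(bundle$demographics$bias,
                             paste(bundle$demographics$bias$group,
                                   bundle$demographics$bias$grouping,
                                   sep = ".")),
                       function(r) list(median = round(r$median, 2),
                                        lower = round(r$lower, 3),
                                        upper = round(r$upper, 3))),
    season_length_days = round(bundle$season$summary$length_days, 1),
    season_length_months = round(bundle$season$summary$length_months, 2),
    trend = as.list(bundle$trend[1, c("slope", "r_squared", "p_value",
                                      "total_advance_days")]))
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(bundle$log, paths[["log"]])
  paths
}
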