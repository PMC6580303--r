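test_that("day-of-year mapping is leap-aware and invertible", {
  expect_equal(doy(as.Date("1997-01-01")), 1L)
  expect_equal(doy(as.Date("2000-12-31")), 366L)
  expect_equal(doy(as.Date("2017-08-15")), 227L)
  expect_equal(doy_date(227L, 2017), as.Date("2017-08-15"))
  expect_equal(doy_date(366L, 2017), as.Date("2017-12-31")) # non-leap clamp
})

test_that("stranding records round-trip through CSV with validation intact", {
  s <- gen_strandings(synthetic_config(seed = 8))
  f <- tempfile(fileext = ".csv")
  readr::write_csv(s, f)
  back <- read_strandings(f)
  expect_equal(nrow(back), nrow(s))
  expect_equal(back$date, s$date)
  expect_equal(back$sex, s$sex)
  expect_equal(back$age_class, s$age_class)
  expect_equal(back$cause, s$cause)
  expect_equal(nrow(validation_report(back)), 0)
})

test_that("invalid stranding rows are rejected with a row-indexed report", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("date,sex,age_class,cause",
               "2010-06-01,M,mature,shark",
               "2010-07-01,X,mature,other",
               "not-a-date,F,immature,shark",
               "2010-08-01,unknown,mature,other",
               "2010-09-01,F,adultish,shark"), f)
  got <- read_strandings(f)
  rep <- validation_report(got)
  expect_equal(nrow(got), 2)       # valid row + flagged unknown-sex row
  expect_setequal(rep$row[rep$action == "rejected"], c(2L, 3L, 5L))
  expect_true(any(rep$field == "sex" & grepl("'X'", rep$reason)))
  expect_true(any(rep$row == 4 & rep$action == "flagged"))
})

test_that("schema errors name the missing columns, empty files parse", {
  f <- tempfile(fileext = ".csv")
  writeLines("date,sex,cause", f)
  expect_error(read_strandings(f), "age_class")
  writeLines("date,sex,age_class,cause", f)
  expect_equal(nrow(read_strandings(f)), 0)
})

test_that("column-name mapping lets readers accept foreign headers", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("StrandDate,Sex,age_class,cause",
               "2010-06-01,M,mature,shark"), f)
  got <- read_strandings(f, col_map = c(date = "StrandDate", sex = "Sex"))
  expect_equal(got$date, as.Date("2010-06-01"))
})

test_that("incident filtering retains exactly the rows matching all criteria", {
  rec <- tibble::tibble(
    date = as.Date(c("2005-06-01", "2005-06-02", "2005-06-03",
                     "1990-06-04", "2005-06-05")),
    species_label = c("white shark", "white shark", "tiger shark",
                      "white shark", "white shark"),
    provoked = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    injurious = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    region = c("California", "California", "California", "California",
               "California"),
    fatal = FALSE)
  kept <- filter_incidents(rec)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$date, rec$date[1:2])
  # idempotence and the all-excluded case
  expect_identical(filter_incidents(kept), kept)
  allprov <- dplyr::mutate(rec, provoked = TRUE)
  expect_equal(nrow(filter_incidents(allprov)), 0)
})

test_that("incident and detection streams round-trip through their readers", {
  cfg <- synthetic_config(seed = 12)
  inc <- gen_incidents(cfg)
  f <- tempfile(fileext = ".csv")
  readr::write_csv(inc, f)
  back <- read_incidents(f)
  expect_equal(back$date, inc$date)
  expect_equal(back$provoked, inc$provoked)
  det <- gen_detections(cfg)$shark
  f2 <- tempfile(fileext = ".csv")
  readr::write_csv(det, f2)
  back2 <- read_detections(f2)
  expect_equal(back2$count, det$count)
  expect_equal(back2$date, det$date)
})

test_that("detection reader enforces nonnegative counts and unique dates", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("date,count", "2010-01-01,3", "2010-01-01,2"), f)
  expect_error(read_detections(f), "strictly increasing")
  writeLines(c("date,count", "2010-01-01,-1"), f)
  expect_error(read_detections(f), "nonnegative")
})

test_that("exclusion rules remove pups and non-shark geriatrics only", {
  recs <- dplyr::bind_rows(
    stranding_row("2010-01-01", age_class = "pup", cause = "shark"),
    stranding_row("2010-01-02", age_class = "pup", cause = "other"),
    stranding_row("2010-01-03", age_class = "geriatric", cause = "shark"),
    stranding_row("2010-01-04", age_class = "geriatric", cause = "other"),
    stranding_row("2010-01-05", age_class = "mature", cause = "other"),
    stranding_row("2010-01-06", age_class = "immature", cause = "shark"))
  kept <- apply_stranding_exclusions(recs)
  expect_equal(kept$age_class, c("geriatric", "mature", "immature"))
  expect_equal(attr(kept, "exclusions"),
               c(pups = 2L, geriatric_nonshark = 1L))
})

test_that("bin assignment follows the floor rule and reports early records", {
  recs <- dplyr::bind_rows(
    stranding_row("1997-05-01"), stranding_row("1999-12-31"),
    stranding_row("2000-01-01"), stranding_row("2017-06-01"),
    stranding_row("1995-01-01"))
  expect_warning(binned <- assign_bins(recs), "1997")
  expect_equal(binned$bin, c(0L, 0L, 1L, 6L))
  expect_equal(nrow(attr(binned, "excluded_early")), 1)
})

test_that("aggregation reproduces configured synthetic cells after exclusion", {
  cells <- tiny_cells(m_shark = 6L, f_shark = 1L, m_other = 8L, f_other = 9L)
  cfg <- synthetic_config(seed = 13, n_bins = 1, cells = cells,
                          season_center = 250, season_width80 = 40,
                          n_pups = 3L, n_geriatric_other = 2L)
  s <- gen_strandings(cfg)
  kept <- apply_stranding_exclusions(s)
  agg <- aggregate_counts(assign_bins(kept))
  expect_equal(agg$grand_total, sum(cells$count))
  joined <- dplyr::left_join(cells, agg$cells,
                             by = c("bin", "sex", "maturity", "cause"))
  expect_equal(joined$count.y, joined$count.x)
  expect_equal(sum(agg$cells$count), agg$grand_total)
})

test_that("per-bin quotient matches the published convention", {
  recs <- counts_to_records(otter_stranding_counts(reconciled = TRUE)$cells)
  recs$maturity <- NULL
  recs2 <- dplyr::bind_rows(lapply(seq_len(nrow(recs)), function(i) {
    stranding_row(paste0(1997 + recs$bin[i] * 3, "-06-01"), sex = recs$sex[i],
                  age_class = "mature", cause = recs$cause[i])
  }))
  agg <- aggregate_counts(assign_bins(recs2))
  expect_equal(round(agg$totals$quotient, 2),
               c(0.33, 0.13, 0.15, 0.12, 0.59, 0.67, 0.67))
  # both proportion definitions are emitted and labelled
  expect_true(all(c("quotient", "prop_shark") %in% names(agg$totals)))
})

test_that("a bin without non-shark strandings yields an undefined quotient", {
  recs <- dplyr::bind_rows(stranding_row("1998-07-01"),
                           stranding_row("1998-08-01"))
  agg <- aggregate_counts(assign_bins(recs))
  expect_true(is.na(agg$totals$quotient))
  expect_equal(agg$totals$prop_shark, 1)
})

test_that("published cell/total inconsistencies are surfaced, not reconciled", {
  cons <- counts_consistency(otter_stranding_counts())
  bad <- dplyr::filter(cons, !consistent)
  expect_setequal(bad$bin, c(1L, 3L, 4L, 5L))
  expect_true(all(bad$cause == "shark"))
  # the reconciled variant matches printed totals exactly
  cons2 <- counts_consistency(otter_stranding_counts(reconciled = TRUE))
  expect_true(all(cons2$consistent))
})

test_that("expanding counts to records conserves every cell", {
  cells <- otter_stranding_counts()$cells
  recs <- counts_to_records(cells)
  expect_equal(nrow(recs), sum(cells$count))
  back <- dplyr::count(recs, bin, sex, maturity, cause)
  joined <- dplyr::left_join(dplyr::filter(cells, count > 0), back,
                             by = c("bin", "sex", "maturity", "cause"))
  expect_equal(joined$n, joined$count)
})
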