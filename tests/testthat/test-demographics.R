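test_that("male maturity-by-cause table reproduces the published 2x2 layout", {
  cells <- otter_stranding_counts()$cells
  recs <- counts_to_records(cells)
  tab <- build_contingency(recs, "maturity", "cause",
                           strata = list(sex = "M"))
  expect_equal(unclass(tab)[1:2, 1:2],
               matrix(c(58L, 28L, 67L, 71L), nrow = 2,
                      dimnames = list(c("mature", "immature"),
                                      c("shark", "other"))),
               ignore_attr = TRUE)
})

test_that("contingency building validates its inputs", {
  recs <- counts_to_records(otter_stranding_counts()$cells)
  expect_error(build_contingency(recs[0, ], "sex", "cause"), "no records")
  onlyM <- recs[recs$sex == "M", ]
  expect_error(build_contingency(onlyM, "sex", "cause"), "F")
  # synthetic conservation: cells in, identical cells out
  cells <- tiny_cells(m_shark = 9L, f_shark = 4L, m_other = 2L, f_other = 6L)
  tab <- build_contingency(counts_to_records(cells), "sex", "cause")
  expect_equal(as.integer(tab), c(9L, 4L, 2L, 6L))
  expect_equal(sum(tab), sum(cells$count))
})

test_that("Yates chi-squared reproduces hand-evaluated statistics", {
  r <- chi_squared(matrix(c(58, 28, 67, 71), nrow = 2))
  expect_equal(round(r$value, 2), 6.92)
  expect_equal(r$df, 1)
  expect_lt(r$p_value, 0.01)

  r0 <- chi_squared(matrix(c(10, 10, 10, 10), nrow = 2))
  expect_equal(r0$value, 0)
  expect_equal(r0$p_value, 1)

  r2 <- chi_squared(matrix(c(20, 5, 5, 20), nrow = 2))
  expect_equal(round(r2$value, 2), 15.68)

  expect_error(chi_squared(matrix(c(0, 0, 5, 5), nrow = 2)), "margin")
})

test_that("chi-squared agrees with the stats oracle on random tables", {
  withr::with_seed(41, {
    for (i in 1:60) {
      tab <- matrix(sample(1:40, 4, replace = TRUE), nrow = 2)
      expect_equal(chi_squared(tab, yates = TRUE)$value,
                   unname(suppressWarnings(
                     stats::chisq.test(tab, correct = TRUE))$statistic),
                   tolerance = 1e-10)
      expect_equal(chi_squared(tab, yates = FALSE)$value,
                   unname(suppressWarnings(
                     stats::chisq.test(tab, correct = FALSE))$statistic),
                   tolerance = 1e-10)
    }
    # r x c Pearson path
    tab3 <- matrix(sample(1:30, 9, replace = TRUE), nrow = 3)
    got <- chi_squared(tab3)
    want <- suppressWarnings(stats::chisq.test(tab3, correct = FALSE))
    expect_equal(got$value, unname(want$statistic), tolerance = 1e-10)
    expect_equal(got$df, 4)
  })
})

test_that("Yates correction never exceeds the uncorrected statistic and
           the statistic is invariant under table symmetries", {
  withr::with_seed(42, {
    for (i in 1:40) {
      tab <- matrix(sample(1:30, 4, replace = TRUE), nrow = 2)
      y <- chi_squared(tab, yates = TRUE)$value
      p <- chi_squared(tab, yates = FALSE)$value
      expect_lte(y, p + 1e-12)
      expect_equal(chi_squared(tab[2:1, ])$value, y, tolerance = 1e-12)
      expect_equal(chi_squared(tab[, 2:1])$value, y, tolerance = 1e-12)
      expect_equal(chi_squared(t(tab))$value, y, tolerance = 1e-12)
    }
  })
})

test_that("rank-sum statistic and exact p match the worked examples", {
  r <- wilcoxon(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$value, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact_enumeration")
  # mirror symmetry
  expect_equal(wilcoxon(c(4, 5, 6), c(1, 2, 3))$value, 9)
  # identical paired samples: zero differences discarded, p = 1
  r2 <- wilcoxon(c(1, 2, 3), c(1, 2, 3), mode = "signed_rank_paired")
  expect_equal(r2$p_value, 1)
  expect_equal(r2$value, 0)
  expect_error(wilcoxon(1:3, 1:4, mode = "signed_rank_paired"),
               "equal-length")
})

test_that("exact Wilcoxon p-values agree with brute-force enumeration", {
  withr::with_seed(43, {
    for (i in 1:20) {
      n1 <- sample(2:5, 1)
      n2 <- sample(2:5, 1)
      x <- sample(1:6, n1, replace = TRUE)  # small pool forces ties
      y <- sample(1:6, n2, replace = TRUE)
      expect_equal(wilcoxon(x, y)$p_value, oracle_rank_sum_p(x, y),
                   tolerance = 1e-12)
      m <- min(n1, n2)
      expect_equal(
        wilcoxon(x[1:m], y[1:m], mode = "signed_rank_paired")$p_value,
        oracle_signed_rank_p(x[1:m], y[1:m]), tolerance = 1e-12)
    }
  })
  # tie-free cases also agree with the stats implementation
  withr::with_seed(44, {
    for (i in 1:10) {
      x <- sample(1:100, 4)
      y <- setdiff(sample(1:100, 10), x)[1:4]
      expect_equal(wilcoxon(x, y)$p_value,
                   stats::wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("large-sample rank-sum p uses the tie-corrected normal approximation", {
  withr::with_seed(45, {
    x <- sample(1:20, 15, replace = TRUE)
    y <- sample(5:25, 15, replace = TRUE)
  })
  got <- wilcoxon(x, y)
  expect_equal(got$method, "normal_approximation")
  want <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
  expect_equal(got$p_value, want$p.value, tolerance = 1e-10)
})

test_that("bootstrap male bias behaves at its fixed points", {
  all_male <- tibble::tibble(sex = rep("M", 20), bin = 0L)
  b <- bootstrap_bias(all_male, bootstrap_config(n_replicates = 200, seed = 1))
  expect_equal(b$median, 1)
  expect_equal(c(b$lower, b$upper), c(1, 1))
  expect_error(bootstrap_bias(all_male[0, ]), "no records")
  expect_error(bootstrap_bias(tibble::tibble(sex = "unknown")), "sex")
  expect_error(bootstrap_bias(tibble::tibble(sex = "M"),
                              grouping = "per_bin"), "bin")
})

test_that("bootstrap median converges to the observed proportion", {
  cells <- otter_stranding_counts()$cells
  mat_other <- counts_to_records(
    dplyr::filter(cells, maturity == "mature", cause == "other"))
  p_hat <- mean(mat_other$sex == "M")
  b <- bootstrap_bias(mat_other, bootstrap_config(n_replicates = 10000,
                                                  seed = 2),
                      grouping = "pooled")
  expect_lt(abs(b$median - p_hat), 0.02)
  expect_true(b$lower <= b$median && b$median <= b$upper)
})

test_that("bootstrap output is seed-reproducible and groupings differ sanely", {
  recs <- counts_to_records(
    dplyr::filter(otter_stranding_counts()$cells, cause == "shark"))
  cfg <- bootstrap_config(n_replicates = 300, seed = 7)
  b1 <- bootstrap_bias(recs, cfg, grouping = "per_bin")
  b2 <- bootstrap_bias(recs, cfg, grouping = "per_bin")
  expect_identical(attr(b1, "replicates"), attr(b2, "replicates"))
  expect_s3_class(attr(b1, "per_bin_observed"), "tbl_df")
  # per-bin weighted pooling centres on the same observed proportion
  b3 <- bootstrap_bias(recs, cfg, grouping = "pooled")
  expect_lt(abs(b1$median - b3$median), 0.05)
})
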