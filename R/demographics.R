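default_factor_levels <- list(
  sex = c("M", "F"),
  maturity = c("mature", "immature"),
  age_class = c("mature", "immature"),
  cause = c("shark", "other")
)

#' Build a contingency table from stranding records
#'
#' Cross-tabulates two categorical record fields into an r x c count table,
#' optionally after filtering to a stratum. Level order follows the field's
#' conventional order (mature before immature, shark before other, M before
#' F) so published 2x2 layouts are reproduced cell-for-cell.
#'
#' @param records Stranding tibble (post-exclusion).
#' @param row_factor,col_factor Column names to cross-tabulate.
#' @param strata Optional named list of `column = value` filters applied
#'   before tabulation, e.g. `list(sex = "M")`.
#' @param levels_row,levels_col Optional explicit level orders.
#' @return An integer matrix with named dimnames and attributes
#'   `row_factor`/`col_factor`. A level with no observations is an error
#'   naming the empty level.
#' @export
build_contingency <- function(records, row_factor, col_factor, strata = NULL,
                              levels_row = NULL, levels_col = NULL) {
  for (col in names(strata)) {
    records <- records[records[[col]] == strata[[col]], ]
  }
  if (nrow(records) == 0) stop("no records after stratum filtering", call. = FALSE)
  lev <- function(field, explicit) {
    vals <- unique(records[[field]])
    if (!is.null(explicit)) return(explicit)
    canon <- default_factor_levels[[field]]
    if (!is.null(canon) && all(vals %in% canon)) canon else sort(vals)
  }
  rl <- lev(row_factor, levels_row)
  cl <- lev(col_factor, levels_col)
  tab <- table(factor(records[[row_factor]], levels = rl),
               factor(records[[col_factor]], levels = cl))
  empty_r <- rl[rowSums(tab) == 0]
  empty_c <- cl[colSums(tab) == 0]
  if (length(empty_r) + length(empty_c) > 0) {
    stop("factor level(s) with no observations: ",
         paste(c(empty_r, empty_c), collapse = ", "), call. = FALSE)
  }
  out <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  attr(out, "row_factor") <- row_factor
  attr(out, "col_factor") <- col_factor
  out
}

#' Chi-squared test of independence
#'
#' Pearson's chi-squared test on an r x c count table, with Yates'
#' continuity correction available (and on by default) for 2x2 tables. The
#' statistic is computed directly from the counts: expected cells
#' `E = rowsum x colsum / n` and statistic `sum((|O - E| - c)^2 / E)` with
#' `c = min(0.5, |O - E|)` under Yates (the standard cap keeps the
#' corrected deviation nonnegative) and `c = 0` otherwise. The p-value uses
#' the chi-squared distribution with `(r - 1)(c - 1)` degrees of freedom.
#'
#' @param tab Count matrix ([build_contingency()] output or any matrix).
#' @param yates Apply the continuity correction (2x2 tables only).
#' @return A one-row tibble: `statistic`, `value`, `df`, `p_value`,
#'   `yates`.
#' @examples
#' chi_squared(matrix(c(58, 28, 67, 71), nrow = 2))
#' @export
chi_squared <- function(tab, yates = TRUE) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be nonnegative", call. = FALSE)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    stop("test undefined: a table margin is zero", call. = FALSE)
  }
  n <- sum(tab)
  E <- outer(rs, cs) / n
  is2x2 <- all(dim(tab) == c(2, 2))
  corr <- if (yates && is2x2) min(0.5, abs(tab - E)) else 0
  stat <- sum((abs(tab - E) - corr)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  tibble::tibble(statistic = "chi_squared", value = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 yates = yates && is2x2)
}

#' Wilcoxon rank tests with exact small-sample enumeration
#'
#' Two-sample rank-sum (Mann-Whitney) and paired signed-rank tests. Ranks
#' use midranks under ties. P-values are exact -- computed by full
#' enumeration of all group assignments (rank sum, combined n <= 12) or all
#' sign assignments (signed rank, <= 12 nonzero pairs) -- and otherwise use
#' the normal approximation with tie correction and a 0.5 continuity
#' correction. Two-sided throughout.
#'
#' The reported rank-sum statistic is the first-sample Mann-Whitney
#' statistic `W = sum of x ranks - n_x(n_x + 1)/2`; the signed-rank
#' statistic is `V = sum of ranks of positive differences` after discarding
#' zero differences (identical samples therefore give `V = 0`, `p = 1`).
#'
#' @param x,y Numeric samples (equal length required for the paired mode).
#' @param mode `"rank_sum"` or `"signed_rank_paired"`.
#' @return A one-row tibble: `statistic`, `value`, `n_x`, `n_y`,
#'   `p_value`, `method`.
#' @examples
#' wilcoxon(c(1, 2, 3), c(4, 5, 6))  # W = 0, exact p = 0.1
#' @export
wilcoxon <- function(x, y, mode = c("rank_sum", "signed_rank_paired")) {
  mode <- match.arg(mode)
  if (mode == "rank_sum") {
    stopifnot(length(x) > 0, length(y) > 0)
    wilcoxon_rank_sum(x, y)
  } else {
    if (length(x) != length(y)) {
      stop("paired mode requires equal-length samples", call. = FALSE)
    }
    wilcoxon_signed_rank(x, y)
  }
}

wilcoxon_rank_sum <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n <= 12) {
    sets <- utils::combn(n, n1)
    base <- n1 * (n1 + 1) / 2
    ws <- apply(sets, 2, function(idx) sum(r[idx])) - base
    p <- min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
    method <- "exact_enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  tibble::tibble(statistic = "W_rank_sum", value = w, n_x = n1, n_y = n2,
                 p_value = p, method = method)
}

wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  n_pairs <- length(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble::tibble(statistic = "V_signed_rank", value = 0,
                          n_x = n_pairs, n_y = n_pairs, p_value = 1,
                          method = "zero_discard"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.numeric(signs %*% r)
    p <- min(1, 2 * min(mean(vs <= v + 1e-9), mean(vs >= v - 1e-9)))
    method <- "exact_enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  tibble::tibble(statistic = "V_signed_rank", value = v, n_x = n_pairs,
                 n_y = n_pairs, p_value = p, method = method)
}

#' Bootstrap resampling configuration
#'
#' @param n_replicates Number of bootstrap replicates (default 1,000, the
#'   study's per-bin replicate count).
#' @param ci_level Central interval level for percentile CIs.
#' @param seed Optional integer seed; when set the bootstrap is exactly
#'   reproducible.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_replicates = 1000L, ci_level = 0.95,
                             seed = NULL) {
  stopifnot(n_replicates >= 1, ci_level > 0, ci_level < 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 ci_level = ci_level, seed = seed),
            class = "bootstrap_config")
}

#' Bootstrap male-bias summary for a stranding stratum
#'
#' Resamples a stratum of sexed stranding records with replacement and
#' summarises the replicate distribution of the male proportion (the
#' study's compositional risk metric) by its median and central percentile
#' interval. With `grouping = "per_bin"` (the default) records are
#' resampled within each multi-year bin and the replicate value is the
#' bin-size-weighted pooled proportion; `"pooled"` resamples the stratum as
#' a whole, which is the aggregation that reproduces the published adult
#' medians from the summary-table counts.
#'
#' @param records Tibble with a `sex` column (`"M"`/`"F"`), and a `bin`
#'   column when `grouping = "per_bin"`.
#' @param cfg A [bootstrap_config()].
#' @param grouping `"per_bin"` or `"pooled"`.
#' @param label Optional stratum label carried into the summary.
#' @return A one-row tibble: `group`, `n_records`, `male_count`, `median`,
#'   `lower`, `upper`, `n_replicates`, `grouping`. The full replicate
#'   vector is attached as attribute `replicates`, and per-bin observed
#'   male proportions as attribute `per_bin_observed` (per-bin grouping
#'   only).
#' @export
bootstrap_bias <- function(records, cfg = bootstrap_config(),
                           grouping = c("per_bin", "pooled"), label = NULL) {
  grouping <- match.arg(grouping)
  if (nrow(records) == 0) stop("stratum has no records", call. = FALSE)
  if (!all(records$sex %in% c("M", "F"))) {
    stop("all records must have sex 'M' or 'F'", call. = FALSE)
  }
  male <- as.integer(records$sex == "M")
  R <- cfg$n_replicates
  run <- function() {
    if (grouping == "pooled") {
      n <- length(male)
      draws <- matrix(sample.int(n, n * R, replace = TRUE), nrow = R)
      rowSums(matrix(male[draws], nrow = R)) / n
    } else {
      if (!"bin" %in% names(records)) {
        stop("per-bin grouping requires a `bin` column", call. = FALSE)
      }
      groups <- split(male, records$bin)
      tot_m <- matrix(0, nrow = R, ncol = 1)
      for (g in groups) {
        n_g <- length(g)
        draws <- matrix(sample.int(n_g, n_g * R, replace = TRUE), nrow = R)
        tot_m <- tot_m + rowSums(matrix(g[draws], nrow = R))
      }
      as.numeric(tot_m) / length(male)
    }
  }
  reps <- if (is.null(cfg$seed)) run() else {
    withr::with_seed(stage_seed(cfg$seed, "bootstrap_bias"), run())
  }
  alpha <- (1 - cfg$ci_level) / 2
  ci <- quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 7)
  out <- tibble::tibble(
    group = if (is.null(label)) NA_character_ else label,
    n_records = length(male), male_count = sum(male),
    median = median(reps), lower = ci[1], upper = ci[2],
    n_replicates = R, grouping = grouping)
  attr(out, "replicates") <- reps
  if (grouping == "per_bin") {
    obs <- vapply(split(male, records$bin), mean, numeric(1))
    attr(out, "per_bin_observed") <- tibble::tibble(
      bin = as.integer(names(obs)), male_prop = unname(obs))
  }
  out
}
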