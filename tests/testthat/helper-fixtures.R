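# Shared fixtures and independent oracles for the test suite.

# A minimal cell table: one bin, known composition.
tiny_cells <- function(bin = 0L, m_shark = 3L, f_shark = 2L,
                       m_other = 4L, f_other = 5L) {
  tibble::tibble(
    bin = bin,
    sex = c("M", "F", "M", "F"),
    maturity = c("mature", "mature", "immature", "immature"),
    cause = c("shark", "shark", "other", "other"),
    count = c(m_shark, f_shark, m_other, f_other))
}

# Shark-only cell table with n records per bin, split over sex x maturity.
shark_cells <- function(n_per_bin) {
  dplyr::bind_rows(lapply(seq_along(n_per_bin) - 1, function(b) {
    n <- n_per_bin[b + 1]
    tibble::tibble(bin = b, sex = rep(c("M", "F"), each = 2),
                   maturity = rep(c("immature", "mature"), 2),
                   cause = "shark",
                   count = c(rep(n %/% 4, 3), n - 3 * (n %/% 4)))
  }))
}

# Stranding records built directly (no generator), for exclusion tests.
stranding_row <- function(date, sex = "M", age_class = "mature",
                          cause = "shark") {
  tibble::tibble(date = as.Date(date), sex = sex, age_class = age_class,
                 cause = cause, alive_at_recovery = TRUE)
}

# Independent brute-force oracle for the two-sided exact rank-sum p-value:
# walks every subset of size n1 via bitmask, recomputing midranks from
# scratch each time.
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ws <- c()
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) != n1) next
    ws <- c(ws, sum(r[bits == 1]) - n1 * (n1 + 1) / 2)
  }
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

# Same idea for the paired signed-rank statistic.
oracle_signed_rank_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    vs[mask + 1] <- sum(r[bits == 1])
  }
  min(1, 2 * min(mean(vs <= v_obs + 1e-9), mean(vs >= v_obs - 1e-9)))
}
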