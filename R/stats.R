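#' Binomial proportion with confidence interval, percent scale
#'
#' Default is the Wald interval `p +/- z * sqrt(p(1-p)/n)`, reported on the
#' 0-100 percent scale and clipped to it. Wald degenerates at p = 0 or 1
#' (zero-width interval) — a documented limitation; the Wilson score interval
#' is available via `method = "wilson"` for boundary-heavy use.
#'
#' @param count Successes (0 <= count <= n).
#' @param n Trials (> 0).
#' @param level Confidence level, default 0.95.
#' @param method `"wald"` or `"wilson"`.
#' @return A list of class `proportion_estimate`: `count`, `n`, `percent`,
#'   `ci_low`, `ci_high`, `ci_level` (unrounded; printed to 2 decimals).
#' @export
#' @examples
#' proportion_ci(5617, 31300) # 17.95% (17.52-18.37)
proportion_ci <- function(count, n, level = 0.95,
                          method = c("wald", "wilson")) {
  method <- match.arg(method)
  count <- unname(count)
  n <- unname(n)
  stopifnot(length(count) == 1, length(n) == 1)
  if (is.na(n) || n <= 0) stop("n must be positive", call. = FALSE)
  if (is.na(count) || count < 0 || count > n) {
    stop("count must lie in [0, n]", call. = FALSE)
  }
  p <- count / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- p - half
    hi <- p + half
  } else {
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- centre - half
    hi <- centre + half
  }
  structure(list(
    count = as.integer(count), n = as.integer(n),
    percent = 100 * p,
    ci_low = 100 * max(0, lo),
    ci_high = 100 * min(1, hi),
    ci_level = level
  ), class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %s%% (%d%% CI %s-%s)\n", x$count, x$n,
              fmt2(x$percent), round(100 * x$ci_level),
              fmt2(x$ci_low), fmt2(x$ci_high)))
  invisible(x)
}

# half-up rounding to 2 decimals for display, matching table conventions
fmt2 <- function(x) sprintf("%.2f", floor(x * 100 + 0.5) / 100)

new_test_result <- function(statistic, p_value, test_name, df = NA_real_) {
  structure(list(statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value),
                 test_name = test_name, df = as.numeric(df)),
            class = "rx_test_result")
}

#' @export
print.rx_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.3g\n", x$test_name, x$statistic,
              if (is.na(x$df)) "" else sprintf(" (df = %g)", x$df), x$p_value))
  invisible(x)
}

#' Two-proportion Pearson chi-square test
#'
#' Pearson chi-square on the 2x2 table, without continuity correction by
#' default (the correction is immaterial at cohort-scale counts but available
#' for completeness). The statistic equals the squared two-proportion
#' z-statistic.
#'
#' @param count1,n1 Successes and trials in arm 1.
#' @param count2,n2 Successes and trials in arm 2.
#' @param correct Apply Yates continuity correction.
#' @return An `rx_test_result` (statistic, df = 1, p value).
#' @export
#' @examples
#' two_proportion_test(5617, 31300, 6650, 41014)
two_proportion_test <- function(count1, n1, count2, n2, correct = FALSE) {
  counts <- c(count1, count2)
  ns <- c(n1, n2)
  if (any(is.na(counts)) || any(is.na(ns)) || any(ns <= 0) ||
      any(counts < 0) || any(counts > ns)) {
    stop("counts must lie in [0, n] with n > 0", call. = FALSE)
  }
  if (sum(counts) == 0 || sum(ns - counts) == 0) {
    stop("both margins of the 2x2 table must be nonzero", call. = FALSE)
  }
  ht <- stats::prop.test(counts, ns, correct = correct)
  new_test_result(unname(ht$statistic), ht$p.value,
                  if (correct) "chi-square (Yates)" else "chi-square",
                  df = unname(ht$parameter))
}

#' Omnibus chi-square on a categories-by-periods contingency table
#'
#' @param table_matrix Integer matrix (categories x periods).
#' @return An `rx_test_result`.
#' @export
omnibus_chisq <- function(table_matrix) {
  ht <- stats::chisq.test(table_matrix, correct = FALSE)
  new_test_result(unname(ht$statistic), ht$p.value, "omnibus chi-square",
                  df = unname(ht$parameter))
}

#' Two-sample t test on monthly volume series
#'
#' Welch by default (no equal-variance assumption across periods); set
#' `var_equal = TRUE` for the pooled-variance test.
#'
#' @param series1,series2 Numeric vectors, each with at least 2 values and
#'   nonzero spread in at least one arm.
#' @param var_equal Pooled variance instead of Welch.
#' @return An `rx_test_result`.
#' @export
t_test_means <- function(series1, series2, var_equal = FALSE) {
  if (length(series1) < 2 || length(series2) < 2) {
    stop("each series needs at least 2 values", call. = FALSE)
  }
  if (stats::sd(series1) == 0 && stats::sd(series2) == 0) {
    if (mean(series1) == mean(series2)) {
      return(new_test_result(0, 1, "t test (degenerate)", df = NA_real_))
    }
    stop("both series are constant; t test undefined", call. = FALSE)
  }
  ht <- stats::t.test(series1, series2, var.equal = var_equal)
  new_test_result(unname(ht$statistic), ht$p.value,
                  if (var_equal) "t test (pooled)" else "t test (Welch)",
                  df = unname(ht$parameter))
}

#' Two-sample Wilcoxon rank-sum test with tie handling
#'
#' Per-patient-per-month utilization counts are heavily tied (median 1, IQR
#' 1-2), so the test must handle ties honestly. For small samples
#' (`n1 + n2 <= exact_limit`) the null distribution of the rank-sum statistic
#' is enumerated exactly over all group assignments of the observed
#' (tied) ranks; otherwise the tie-corrected normal approximation is used:
#' `z = (W - n1(N+1)/2) / sqrt(n1 n2 / (N(N-1)) * (sum(r^2) - N(N+1)^2/4))`
#' with `r` the midranks. An all-tied sample carries no ordering information:
#' p = 1 with a warning.
#'
#' @param series1,series2 Nonempty numeric vectors.
#' @param exact_limit Largest combined sample size for exact enumeration.
#' @return An `rx_test_result`; the statistic is the rank sum `W` of
#'   `series1` (exact) or the z statistic (approximate).
#' @export
wilcoxon_rank_sum <- function(series1, series2, exact_limit = 12) {
  x <- as.numeric(series1)
  y <- as.numeric(series2)
  if (!length(x) || !length(y)) stop("both series must be nonempty", call. = FALSE)
  all_v <- c(x, y)
  n1 <- length(x)
  n <- length(all_v)
  if (length(unique(all_v)) == 1L) {
    warning("all values tied across both samples; rank-sum test is uninformative")
    return(new_test_result(sum(rank(all_v)[seq_len(n1)]), 1,
                           "Wilcoxon rank-sum (degenerate)"))
  }
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2

  if (n <= exact_limit) {
    combos <- utils::combn(n, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
    return(new_test_result(w_obs, p, "Wilcoxon rank-sum (exact)"))
  }
  n2 <- length(y)
  tie_term <- sum(r^2) - n * (n + 1)^2 / 4
  sigma2 <- n1 * n2 / (n * (n - 1)) * tie_term
  z <- (w_obs - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  new_test_result(z, min(1, p), "Wilcoxon rank-sum (normal approx.)")
}
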