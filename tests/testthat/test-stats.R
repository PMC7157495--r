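test_that("Wald intervals reproduce cohort-scale printed values to 2 dp", {
  r2 <- function(x) round(x, 2)
  e1 <- proportion_ci(5617, 31300)
  expect_equal(r2(e1$percent), 17.95)
  expect_equal(r2(c(e1$ci_low, e1$ci_high)), c(17.52, 18.37))
  e2 <- proportion_ci(6650, 41014)
  expect_equal(r2(e2$percent), 16.21)
  expect_equal(r2(c(e2$ci_low, e2$ci_high)), c(15.86, 16.57))
})

test_that("Wald boundary degeneracy is as documented; Wilson is not degenerate", {
  e <- proportion_ci(0, 10)
  expect_equal(c(e$percent, e$ci_low, e$ci_high), c(0, 0, 0))
  w <- proportion_ci(0, 10, method = "wilson")
  expect_gt(w$ci_high, 0)
  expect_error(proportion_ci(1, 0), "positive")
  expect_error(proportion_ci(11, 10), "count")
})

test_that("chi-square test is symmetric, nonnegative, and equals z^2", {
  a <- two_proportion_test(30, 100, 50, 120)
  b <- two_proportion_test(50, 120, 30, 100)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_gte(a$statistic, 0)
  # algebraic identity with the two-proportion z statistic
  p1 <- 30 / 100; p2 <- 50 / 120; pp <- 80 / 220
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 100 + 1 / 120))
  expect_equal(a$statistic, z^2)

  ident <- two_proportion_test(50, 100, 50, 100)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
})

test_that("chi-square agrees with stats::chisq.test and is sane vs Fisher", {
  tab <- matrix(c(3, 7, 7, 3), nrow = 2)
  ours <- two_proportion_test(3, 10, 7, 10)
  ref <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
  # the exact conditional reference for this table
  fisher <- stats::fisher.test(tab)$p.value
  expect_lt(abs(ours$p_value - fisher), 0.15)
  expect_error(two_proportion_test(0, 10, 0, 10), "margin")
})

test_that("type-I error of the two-proportion test is calibrated", {
  set.seed(12345)
  reps <- 1000
  x1 <- stats::rbinom(reps, 500, 0.2)
  x2 <- stats::rbinom(reps, 500, 0.2)
  rej <- vapply(seq_len(reps), function(i) {
    two_proportion_test(x1[i], 500, x2[i], 500)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("t test compares monthly volume series", {
  x <- c(10, 11, 12, 13)
  expect_equal(t_test_means(x, x)$p_value, 1)
  set.seed(5)
  a <- stats::rnorm(11, 4200, 200)
  expect_lt(t_test_means(a, a + 1000)$p_value, 1e-3)
  ref <- stats::t.test(a, a * 1.01)
  ours <- t_test_means(a, a * 1.01)
  expect_equal(ours$p_value, ref$p.value)
  expect_error(t_test_means(1, c(1, 2)), "at least 2")
})

test_that("monthly series simulated to the reported moments give p near .06", {
  # two 11-month arms with means 4284.64 / 4121.00 and SDs 200.68 / 180.74:
  # standardize draws to hit those moments exactly, then Welch-test
  set.seed(99)
  standardize <- function(n, m, s) {
    z <- stats::rnorm(n)
    m + s * (z - mean(z)) / stats::sd(z)
  }
  p <- t_test_means(standardize(11, 4284.64, 200.68),
                    standardize(11, 4121.00, 180.74))$p_value
  expect_gt(p, 0.03)
  expect_lt(p, 0.09)
})

test_that("Wilcoxon rank-sum handles ties exactly at small n", {
  x <- c(1, 1, 1, 2, 2)
  y <- c(1, 1, 2, 2, 2)
  got <- wilcoxon_rank_sum(x, y)
  # exhaustive enumeration oracle over all 10-choose-5 group assignments
  r <- rank(c(x, y))
  combos <- utils::combn(10, 5)
  w_all <- colSums(matrix(r[combos], nrow = 5))
  mu <- 5 * 11 / 2
  w_obs <- sum(r[1:5])
  p_exact <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  expect_equal(got$p_value, p_exact)
})

test_that("Wilcoxon large-sample approximation matches the reference with ties", {
  set.seed(21)
  x <- sample(1:3, 60, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  y <- sample(1:3, 80, replace = TRUE, prob = c(0.5, 0.35, 0.15))
  ours <- wilcoxon_rank_sum(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Wilcoxon extremes: identical, dominated, and all-tied inputs", {
  set.seed(31)
  x <- stats::rnorm(30)
  expect_equal(wilcoxon_rank_sum(x, x)$p_value, 1, tolerance = 1e-12)
  y <- stats::rnorm(50)
  expect_lt(wilcoxon_rank_sum(y, y + 10)$p_value, 0.01)
  expect_warning(got <- wilcoxon_rank_sum(rep(1, 5), rep(1, 7)), "tied")
  expect_equal(got$p_value, 1)
})
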