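# Outlier screen, test selection, Mann-Whitney enumeration, correlation,
# stepwise regression.

test_that("single-pass 2-SD outlier screen matches hand arithmetic", {
  expect_equal(remove_outliers(c(1, 2, 3))$values, c(1, 2, 3))
  # n = 5: |10 - 2| = 8 < 2 * 4.472 -> nothing removed (the screen can be inert)
  r5 <- remove_outliers(c(0, 0, 0, 0, 10))
  expect_equal(r5$values, c(0, 0, 0, 0, 10))
  expect_length(r5$removed, 0)
  # n = 10: |30 - 3| = 27 > 2 * 9.487 -> 30 removed
  r10 <- remove_outliers(c(rep(0, 9), 30))
  expect_equal(r10$values, rep(0, 9))
  expect_equal(r10$removed, 10L)
  # zero SD removes nothing; n < 3 errors
  expect_length(remove_outliers(rep(5, 4))$removed, 0)
  expect_error(remove_outliers(c(1, 2)), "at least 3")
})

test_that("Mann-Whitney U matches exhaustive enumeration for small samples", {
  set.seed(9)
  for (i in 1:6) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    x <- round(rnorm(n1, 0, 2), 1)
    y <- round(rnorm(n2, 1, 2), 1)
    got <- mann_whitney_u(x, y)
    expect_equal(got$method, "exact enumeration")
    expect_equal(got$p, oracle_mwu_p(x, y), tolerance = 1e-12)
  }
  # tie-free case also agrees with the standard exact implementation
  x <- c(1.1, 2.3, 3.7, 5.2); y <- c(0.4, 2.9, 6.1, 7.4, 8.8)
  expect_equal(mann_whitney_u(x, y)$p,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("identical samples compare with zero percent difference and p = 1", {
  a <- c(1, 2, 3, 4, 5)
  cmp <- compare_groups(a, a)
  expect_equal(cmp$percent_difference, 0)
  expect_equal(cmp$p, 1, tolerance = 1e-12)
})

test_that("test selection follows the normality/variance decision rule", {
  set.seed(21)
  a <- rnorm(12); b <- rnorm(12, 0.5)
  expect_equal(compare_groups(a, b)$test, "Student t")
  b_wide <- rnorm(12, 0.5, 8)
  cmp <- compare_groups(a, b_wide)
  expect_true(cmp$test %in% c("Welch t", "Mann-Whitney U"))
  # grossly non-normal sample routes to Mann-Whitney
  c_skew <- c(rep(0.01, 10), 100, 200)
  expect_equal(compare_groups(a, c_skew)$test, "Mann-Whitney U")
})

test_that("compare_groups is symmetric under group swap", {
  set.seed(4)
  a <- rnorm(10, 10); b <- rnorm(10, 12)
  c1 <- compare_groups(a, b)
  c2 <- compare_groups(b, a)
  expect_equal(c1$p, c2$p, tolerance = 1e-12)
  expect_equal(sign(c1$percent_difference), -sign(c2$percent_difference))
})

test_that("cortical thickness group means give a 12.9% control-referenced difference", {
  # arithmetic on the summary means: (0.70 - 0.61) / 0.70 * 100
  set.seed(2)
  a <- 0.70 + rnorm(10, 0, 1e-9)
  b <- 0.61 + rnorm(10, 0, 1e-9)
  cmp <- compare_groups(a, b)
  expect_equal(cmp$percent_difference, (0.70 - 0.61) / 0.70 * 100,
               tolerance = 1e-4)
  expect_equal(round(cmp$percent_difference, 1), 12.9)
})

test_that("pearson_r matches the direct covariance formula and cor.test", {
  x <- c(1, 2, 4, 7, 11); y <- c(0.8, 2.4, 3.1, 8.2, 9.9)
  got <- pearson_r(x, y)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, num / den, tolerance = 1e-12)
  ct <- stats::cor.test(x, y)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
  # perfectly linear pair
  expect_equal(pearson_r(1:5, 2 * (1:5) + 3)$r, 1)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
})

test_that("r = -0.697 explains 48.6% of variance", {
  expect_equal(round(100 * r_squared(-0.697), 1), 48.6)
})

test_that("stepwise regression enters a perfect single predictor with R2 = 1", {
  x <- seq_len(20)
  m <- suppressWarnings(forward_stepwise(2 * x, list(x = x)))  # perfect fit
  expect_equal(m$entered, "x")
  expect_equal(m$r2, 1, tolerance = 1e-12)
})

test_that("stepwise selects the informative candidate and ignores noise", {
  set.seed(31)
  n <- 50
  c1 <- rnorm(n)
  y <- 0.9 * c1 + rnorm(n, 0, sqrt(1 - 0.81))
  c2 <- rnorm(n)
  m <- forward_stepwise(y, list(c1 = c1, c2 = c2))
  # oracle: exhaustive comparison of the two single-predictor fits
  p1 <- summary(lm(y ~ c1))$coefficients[2, 4]
  p2 <- summary(lm(y ~ c2))$coefficients[2, 4]
  expect_lt(p1, p2)
  expect_equal(m$entered[1], "c1")
  expect_false("c2" %in% m$entered)
  expect_equal(unname(m$entry_p["c1"]), p1, tolerance = 1e-9)
})

test_that("alpha_enter = 1 reduces stepwise to ordering by single-step p", {
  set.seed(32)
  n <- 40
  c1 <- rnorm(n); c2 <- rnorm(n)
  y <- 0.8 * c1 + 0.3 * c2 + rnorm(n, 0, 0.5)
  m <- forward_stepwise(y, list(c1 = c1, c2 = c2), alpha_enter = 1)
  expect_equal(m$entered, c("c1", "c2"))
})

test_that("collinear candidates are skipped with a warning", {
  set.seed(33)
  x <- rnorm(30)
  y <- x + rnorm(30, 0, 0.1)
  expect_warning(m <- forward_stepwise(y, list(a = x, b = 2 * x)),
                 "collinear")
  expect_length(m$entered, 1)
})
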