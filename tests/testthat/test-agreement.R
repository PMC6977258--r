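test_that("perfect agreement gives ICC 1; constant data warns instead of NaN", {
  r <- icc21(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$icc, 1)
  expect_equal(r$band, "excellent")
  expect_warning(r0 <- icc21(rep(2, 4), rep(2, 4)), "identical")
  expect_equal(r0$icc, 1)
})

test_that("a constant offset lowers the ICC exactly as the ANOVA decomposition says", {
  r <- icc21(1:4, 2:5)
  # hand decomposition: MSR = 10/3, MSC = 2, MSE = 0 -> ICC = 10/13
  expect_equal(r$icc, 10 / 13, tolerance = 1e-12)
  expect_lt(r$icc, 1)
})

test_that("ICC(2,1) point estimate and CI match an independent implementation", {
  x <- c(1.1, 2.3, 3.1, 4.0, 5.2, 6.1)
  y <- c(1.4, 2.1, 3.6, 3.9, 5.8, 6.0)
  r <- icc21(x, y)
  # frozen from pingouin.intraclass_corr ICC(A,1) on the same table
  expect_equal(r$icc, 0.9817658349, tolerance = 1e-9)
  expect_equal(round(r$ci95, 2), c(0.89, 1.00))
  expect_lte(r$ci95[1], r$icc); expect_gte(r$ci95[2], r$icc)
})

test_that("ICC equals the aov-based variance decomposition on random tables", {
  withr::local_seed(61)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    x <- rnorm(n); y <- x + rnorm(n, sd = runif(1, 0.05, 1)) + rnorm(1, 0, 0.3)
    expect_equal(icc21(x, y)$icc, oracle_icc21(x, y), tolerance = 1e-10)
  }
})

test_that("ICC interpretation bands follow the printed cutpoints", {
  expect_equal(interpret_icc(0.85), "excellent")
  expect_equal(interpret_icc(0.510), "moderate")
  expect_equal(interpret_icc(0.701), "good")
  expect_equal(interpret_icc(0.562), "moderate")
  expect_equal(interpret_icc(0.20), "poor")
  expect_equal(interpret_icc(0.21), "fair")
  expect_equal(interpret_icc(0.40), "fair")
  expect_equal(interpret_icc(0.41), "moderate")
  expect_warning(b <- interpret_icc(-0.3), "negative")
  expect_equal(b, "poor")
  expect_error(interpret_icc(1.2), "\\[-1, 1\\]")
})

test_that("Bland-Altman limits follow the 1.96 SD construction", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa, c(0, 0))

  x <- c(0, 1, 2); y <- c(1, 1, 1)  # diffs -1, 0, 1
  ba <- bland_altman(x, y)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa, c(-1.96, 1.96))
  expect_equal(format_loa(ba), "-1.96-1.96")
  expect_equal(diff(ba$loa), 2 * 1.96 * ba$sd_diff)
})

test_that("the limits of agreement contain about 95% of Gaussian differences", {
  withr::local_seed(71)
  x <- rnorm(2000, 10, 1); y <- x + rnorm(2000, 0.1, 0.5)
  ba <- bland_altman(x, y)
  cover <- mean(ba$diffs >= ba$loa[1] & ba$diffs <= ba$loa[2])
  expect_lt(abs(cover - 0.95), 3 * sqrt(0.95 * 0.05 / 2000))
})

test_that("paired t-test of identical measurements is exactly null", {
  r <- paired_method_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("the group t-test separates the published D distributions with near-certain power", {
  withr::local_seed(81)
  rejections <- replicate(200, {
    b <- rnorm(24, 1.24, 0.35); m <- rnorm(22, 0.69, 0.13)
    independent_group_test(b, m)$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.99)
})

test_that("session ANOVA is null-calibrated for exchangeable sessions", {
  withr::local_seed(91)
  ns <- replicate(100, {
    cols <- list(a = rnorm(46, 1, 0.37), b = rnorm(46, 1, 0.37),
                 c = rnorm(46, 1, 0.37))
    repeated_measure_tests(cols)$anova$p_value > 0.05
  })
  expect_gte(mean(ns), 0.90)
})

test_that("repeated-measure battery reports Shapiro, Levene and ANOVA", {
  withr::local_seed(95)
  cols <- list(r1 = rnorm(30), r2 = rnorm(30), r3 = rnorm(30))
  r <- repeated_measure_tests(cols)
  expect_equal(nrow(r$shapiro), 3)
  expect_true(all(r$shapiro$W <= 1))
  expect_true(r$levene$p_value >= 0 && r$levene$p_value <= 1)
  expect_error(repeated_measure_tests(list(a = rep(1, 5), b = rnorm(5))),
               "degenerate")
})
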