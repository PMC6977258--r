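test_that("AUC handles the degenerate extremes", {
  lab <- c(rep("benign", 4), rep("malignant", 4))
  perfect <- labeled_scores(c(2, 2.1, 2.2, 2.3, 0.5, 0.6, 0.7, 0.8), lab)
  expect_equal(roc_auc(perfect)$auc, 1.0)
  flat <- labeled_scores(rep(1, 8), lab)
  expect_equal(roc_auc(flat)$auc, 0.5)
  expect_error(labeled_scores(1:4, rep("benign", 4)), "both classes")
})

test_that("AUC equals exhaustive concordant-pair counting, including ties", {
  vals <- c(1.0, 1.2, 1.2, 0.8, 0.9, 1.2)
  lab <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  sc <- labeled_scores(vals, lab)
  expect_equal(roc_auc(sc)$auc, oracle_auc(vals, lab))

  withr::local_seed(17)
  for (i in 1:25) {
    n <- sample(6:14, 1)
    v <- sample(seq(0.5, 2, by = 0.25), n, replace = TRUE)  # forces ties
    l <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(l) < 2 || sum(!l) < 2) next
    expect_equal(roc_auc(labeled_scores(v, l))$auc, oracle_auc(v, l))
  }
})

test_that("negating scores and flipping direction leaves diagnostics unchanged", {
  withr::local_seed(19)
  v <- c(rnorm(10, 1.2, 0.3), rnorm(8, 0.7, 0.2))
  l <- rep(c(FALSE, TRUE), c(10, 8))
  a <- youden_optimal(labeled_scores(v, l, "low_malignant"))
  b <- youden_optimal(labeled_scores(-v, l, "high_malignant"))
  expect_equal(a$auc, b$auc)
  expect_equal(a$youden_j, b$youden_j)
  expect_equal(a$sens, b$sens)
  expect_equal(a$spec, b$spec)
  expect_equal(a$cutoff, -b$cutoff)
})

test_that("Youden cutoff matches exhaustive threshold search", {
  vals <- c(0.55, 0.61, 0.70, 0.74, 0.80, 0.95, 1.10, 1.24, 1.30, 1.42)
  lab <- c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  d <- youden_optimal(labeled_scores(vals, lab))
  o <- oracle_youden(vals, lab)
  expect_equal(d$cutoff, o$cutoff)
  expect_equal(d$youden_j, o$j)
  expect_equal(d$sens / 100, o$sens)

  withr::local_seed(23)
  for (i in 1:15) {
    v <- round(runif(12, 0.5, 1.5), 2)
    l <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    if (sum(l) < 2 || sum(!l) < 2) next
    d <- youden_optimal(labeled_scores(v, l))
    o <- oracle_youden(v, l)
    expect_equal(d$cutoff, o$cutoff)
    expect_equal(d$youden_j, o$j, tolerance = 1e-12)
  }
})

test_that("perfect separation gives Youden index 1", {
  lab <- rep(c(FALSE, TRUE), each = 4)
  d <- youden_optimal(labeled_scores(c(2, 2.2, 2.4, 2.6, 1, 1.1, 1.2, 1.3),
                                     lab))
  expect_equal(d$youden_j, 1)
  expect_equal(d$sens, 100)
  expect_equal(d$spec, 100)
})

test_that("confusion metrics follow the standard definitions", {
  m <- confusion_metrics(21, 1, 22, 2)
  expect_equal(round(m$sens, 2), 95.45)
  expect_equal(round(m$spec, 2), 91.67)
  expect_equal(round(m$accuracy, 2), round(100 * 43 / 46, 2))

  all_right <- confusion_metrics(10, 0, 12, 0)
  expect_true(all(unlist(all_right[c("sens", "spec", "ppv", "npv",
                                     "accuracy")]) == 100))
  expect_equal(round(confusion_metrics(20, 2, 22, 2)$ppv, 2), 90.91)

  none_pos <- confusion_metrics(0, 5, 5, 0)
  expect_true(is.na(none_pos$ppv))
  expect_equal(none_pos$undefined, "ppv")
  expect_error(confusion_metrics(-1, 2, 3, 4), "non-negative")
})

test_that("DeLong test of a marker against itself is exactly null", {
  withr::local_seed(29)
  v <- rnorm(20); l <- rep(c(TRUE, FALSE), 10)
  r <- delong_test(labeled_scores(v, l, "high_malignant"),
                   labeled_scores(v, l, "high_malignant"))
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)
})

test_that("DeLong covariance equals the grouped jackknife on a 12-subject set", {
  withr::local_seed(31)
  l <- rep(c(TRUE, FALSE), each = 6)
  s1 <- rnorm(12) + l * 0.8
  s2 <- 0.6 * s1 + rnorm(12, sd = 0.7)
  dl <- ivimroi:::delong_auc_cov(cbind(s1, s2), l)
  jk <- oracle_jackknife_cov(s1, s2, l)
  expect_equal(unname(dl$cov), unname(jk), tolerance = 1e-6)
})

test_that("swapping the two markers negates z and keeps p", {
  withr::local_seed(37)
  l <- rep(c(TRUE, FALSE), c(9, 11))
  a <- labeled_scores(rnorm(20) + l, l, "high_malignant")
  b <- labeled_scores(rnorm(20) + 0.5 * l, l, "high_malignant")
  r1 <- delong_test(a, b); r2 <- delong_test(b, a)
  expect_equal(r1$z, -r2$z)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("DeLong AUC, variance and p agree with pROC", {
  skip_if_not_installed("pROC")
  withr::local_seed(41)
  l <- rep(c(TRUE, FALSE), c(15, 17))
  v1 <- rnorm(32) + l * 1.2
  v2 <- rnorm(32) + l * 0.8
  s1 <- labeled_scores(v1, l, "high_malignant")
  s2 <- labeled_scores(v2, l, "high_malignant")
  r1 <- roc_auc(s1)
  pr1 <- pROC::roc(l, v1, direction = "<", quiet = TRUE)
  expect_equal(r1$auc, as.numeric(pROC::auc(pr1)), tolerance = 1e-12)
  expect_equal(r1$auc_var, pROC::var(pr1, method = "delong"),
               tolerance = 1e-12)
  pr2 <- pROC::roc(l, v2, direction = "<", quiet = TRUE)
  pt <- pROC::roc.test(pr1, pr2, method = "delong", paired = TRUE)
  mt <- delong_test(s1, s2)
  expect_equal(mt$p_value, pt$p.value, tolerance = 1e-10)
})

test_that("DeLong p agrees with a stratified bootstrap oracle on large samples", {
  withr::local_seed(43)
  n <- 200
  l <- rep(c(TRUE, FALSE), each = n)
  v1 <- rnorm(2 * n) + l * 0.5
  v2 <- rnorm(2 * n) + l * 0.35
  s1 <- labeled_scores(v1, l, "high_malignant")
  s2 <- labeled_scores(v2, l, "high_malignant")
  dl <- delong_test(s1, s2)

  rank_auc <- function(v, lab) {
    r <- rank(v)
    (sum(r[lab]) - sum(lab) * (sum(lab) + 1) / 2) / (sum(lab) * sum(!lab))
  }
  pos <- which(l); neg <- which(!l)
  diffs <- replicate(2000, {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    rank_auc(v1[idx], l[idx]) - rank_auc(v2[idx], l[idx])
  })
  d0 <- rank_auc(v1, l) - rank_auc(v2, l)
  z_boot <- d0 / sd(diffs)
  p_boot <- 2 * pnorm(-abs(z_boot))
  expect_lt(abs(dl$p_value - p_boot), 0.02)
})

test_that("logistic coefficients match a from-scratch Newton-Raphson oracle", {
  x1 <- c(0.9, 1.1, 1.4, 0.6, 1.8, 0.7, 1.2, 0.8, 1.6, 1.0)
  x2 <- c(30, 42, 38, 25, 45, 28, 33, 22, 40, 36)
  y <- c(1, 0, 0, 1, 0, 0, 1, 1, 0, 1)
  fit <- logistic_combine(data.frame(a = x1, b = x2), y)
  beta <- oracle_logistic(cbind(x1, x2), y)
  expect_equal(unname(fit$coefficients), unname(beta), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("single-marker logistic reproduces the marker's AUC and nesting helps in-sample", {
  withr::local_seed(47)
  l <- rep(c(TRUE, FALSE), c(12, 14))
  d <- rnorm(26) - l * 1.0
  f <- rnorm(26) - l * 0.5
  single <- logistic_combine(data.frame(d = d), l)
  expect_equal(single$diag$auc, roc_auc(labeled_scores(d, l))$auc)

  both <- logistic_combine(data.frame(d = d, f = f), l)
  expect_gte(both$diag$auc + 1e-12,
             max(roc_auc(labeled_scores(d, l))$auc,
                 roc_auc(labeled_scores(f, l))$auc))
})

test_that("perfect separation is flagged as non-convergence", {
  l <- rep(c(TRUE, FALSE), each = 5)
  x <- c(1:5, 11:15)
  fit <- logistic_combine(data.frame(x = x), l)
  expect_false(fit$converged)
})
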