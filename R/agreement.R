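#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC — the
#' standard model for test-retest and inter-rater agreement of continuous
#' measurements. From the two-way ANOVA mean squares of an n-subject x
#' k-rater table (MSR rows/subjects, MSC columns/raters, MSE residual):
#'
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))
#'
#' with the 95% confidence interval from the F-distribution method of
#' McGraw & Wong.
#'
#' @param x,y Paired measurements from two raters/sessions (same subjects,
#'   same units), each length n >= 3. Alternatively pass a single n x k
#'   matrix as `x`.
#' @param conf_level Confidence level for the interval.
#' @return List of class `icc_result`: `icc`, `ci95` (low, high), `model`
#'   (`"ICC(2,1)"`), `band` (see [interpret_icc()]), `ms` (the mean
#'   squares), `n`, `k`.
#' @examples
#' icc21(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
icc21 <- function(x, y = NULL, conf_level = 0.95) {
  ratings <- if (is.null(y)) as.matrix(x) else cbind(x, y)
  if (anyNA(ratings)) stop("paired measurements must not contain missing values")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3) stop("need at least 3 subjects")
  if (k < 2) stop("need at least 2 raters/sessions")

  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((ratings - grand)^2)
  SSE <- SST - SSR - SSC
  if (SST < .Machine$double.eps * max(1, grand^2) * n * k) {
    warning("zero total variance: identical measurements, ICC defined as 1")
    return(structure(list(icc = 1, ci95 = c(1, 1), model = "ICC(2,1)",
                          band = interpret_icc(1),
                          ms = c(MSR = 0, MSC = 0, MSE = 0), n = n, k = k),
                     class = "icc_result"))
  }
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- max(SSE / ((n - 1) * (k - 1)), 0)

  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))

  # McGraw & Wong F-method CI for ICC(A,1)
  alpha <- 1 - conf_level
  if (MSE <= 0) {
    ci <- c(icc, icc)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    bq <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + bq * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (bq * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(max(-1, lower), min(1, upper))
  }
  band <- interpret_icc(max(min(icc, 1), -1))
  structure(list(icc = icc, ci95 = ci, model = "ICC(2,1)", band = band,
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE), n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s = %.3f (95%% CI %.3f-%.3f), %s agreement\n",
              x$model, x$icc, x$ci95[1], x$ci95[2], x$band))
  invisible(x)
}

#' Interpret an ICC value on the conventional agreement bands
#'
#' 0.00-0.20 poor, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 good,
#' 0.81-1.00 excellent (closed two-decimal intervals; the boundary 0.20 is
#' poor, 0.21 is fair). Negative ICCs map to poor with a warning.
#'
#' @param icc A value in \[-1, 1\].
#' @return One of `"poor"`, `"fair"`, `"moderate"`, `"good"`, `"excellent"`.
#' @examples
#' interpret_icc(0.85)   # excellent
#' interpret_icc(0.510)  # moderate
#' @export
interpret_icc <- function(icc) {
  if (length(icc) != 1 || is.na(icc) || icc < -1 || icc > 1) {
    stop("icc must be a single value in [-1, 1]")
  }
  if (icc < 0) {
    warning("negative ICC interpreted as poor agreement")
    return("poor")
  }
  if (icc <= 0.20) "poor"
  else if (icc <= 0.40) "fair"
  else if (icc <= 0.60) "moderate"
  else if (icc <= 0.80) "good"
  else "excellent"
}

#' Bland-Altman 95% limits of agreement
#'
#' Differences d_i = x_i - y_i against their means; the limits of agreement
#' are mean(d) +/- 1.96 sd(d), containing about 95% of the differences when
#' they are Gaussian.
#'
#' @param x,y Paired measurements (length n >= 3, same units).
#' @return List of class `bland_altman_result`: `mean_diff`, `sd_diff`,
#'   `loa` (low, high), `means`, `diffs`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be the same length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("paired measurements must not contain missing values")
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  structure(list(mean_diff = md, sd_diff = sdd,
                 loa = c(md - 1.96 * sdd, md + 1.96 * sdd),
                 means = (x + y) / 2, diffs = d, n = length(d)),
            class = "bland_altman_result")
}

#' Format limits of agreement as a printed "low-high" span
#'
#' @param ba A `bland_altman_result`.
#' @param digits Decimals (default 2, the conventional table precision).
#' @return Character scalar like `"-0.15-0.16"`.
#' @export
format_loa <- function(ba, digits = 2) {
  sprintf("%.*f-%.*f", digits, ba$loa[1], digits, ba$loa[2])
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.4g, 95%% LoA %s (n = %d)\n",
              x$mean_diff, format_loa(x, 3), x$n))
  invisible(x)
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on the absolute deviations from the group means (Levene's
#' original, mean-centred form).
#'
#' @param values Numeric vector.
#' @param groups Factor of group membership.
#' @return List with `statistic` (F), `df`, `p_value`.
#' @export
levene_test <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  centered <- abs(values - stats::ave(values, groups))
  a <- stats::anova(stats::lm(centered ~ groups))
  list(statistic = a$`F value`[1], df = a$Df, p_value = a$`Pr(>F)`[1])
}

#' Distribution and repeated-measurement tests for a measurement set
#'
#' The statistical battery applied to each parameter/method: Shapiro-Wilk
#' normality per repeated-measurement column, Levene homogeneity across
#' columns, and one-way ANOVA across the repeated measurement sessions
#' (whose F should be near 1 when sessions are exchangeable).
#'
#' @param columns Named list of numeric vectors (one per delineation, e.g.
#'   reader 1, reader 2 session 1, reader 2 session 2), equal lengths >= 3.
#' @return List with `shapiro` (data.frame column/W/p), `levene`,
#'   `anova` (F and p across columns).
#' @export
repeated_measure_tests <- function(columns) {
  stopifnot(is.list(columns), length(columns) >= 2)
  n <- unique(vapply(columns, length, 0L))
  if (length(n) != 1 || n < 3) stop("columns must share one length >= 3")
  if (any(vapply(columns, function(v) stats::sd(v) == 0, TRUE))) {
    stop("degenerate (zero-variance) column; tests undefined")
  }
  sh <- do.call(rbind, lapply(names(columns), function(nm) {
    s <- stats::shapiro.test(columns[[nm]])
    data.frame(column = nm, W = unname(s$statistic), p_value = s$p.value)
  }))
  vals <- unlist(columns, use.names = FALSE)
  grp <- factor(rep(names(columns), each = n), levels = names(columns))
  lev <- levene_test(vals, grp)
  a <- stats::anova(stats::lm(vals ~ grp))
  list(shapiro = sh, levene = lev,
       anova = list(statistic = a$`F value`[1], df = a$Df,
                    p_value = a$`Pr(>F)`[1]))
}

#' Paired and independent group comparisons
#'
#' `paired_method_test()` compares the same nodules measured by two methods
#' (paired t-test); `independent_group_test()` compares benign and malignant
#' nodules (independent two-sample t-test, pooled variance, as appropriate
#' after variance homogeneity has been checked).
#'
#' @param x,y Numeric vectors; paired (same subjects) for the paired test.
#' @return List with `statistic`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
paired_method_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("paired test needs two equal-length vectors, n >= 3")
  }
  if (stats::sd(x - y) == 0) {
    return(list(statistic = 0, df = length(x) - 1, p_value = 1,
                mean_x = mean(x), mean_y = mean(y)))
  }
  t <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(t$statistic), df = unname(t$parameter),
       p_value = t$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' @rdname paired_method_test
#' @param var_equal Pool the variances (classical independent t-test).
#' @export
independent_group_test <- function(x, y, var_equal = TRUE) {
  if (length(x) < 3 || length(y) < 3) stop("each group needs n >= 3")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    stop("degenerate (zero-variance) groups; t-test undefined")
  }
  t <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(t$statistic), df = unname(t$parameter),
       p_value = t$p.value, mean_x = mean(x), mean_y = mean(y))
}
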