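#' Labelled diagnostic marker scores
#'
#' Couples a continuous per-nodule marker with the binary reference label
#' (malignant = positive class) and the marker's direction: for D, f and ADC
#' low values indicate malignancy, so scores are negated internally to keep
#' the AUC >= 0.5 convention; cutoffs are always reported on the original
#' marker scale.
#'
#' @param values Numeric marker values, one per nodule.
#' @param labels Malignancy labels: logical, 0/1, or a factor/character
#'   vector with levels benign/malignant.
#' @param direction `"low_malignant"` (default for D, f, ADC) or
#'   `"high_malignant"`.
#' @return List of class `labeled_scores` with `values`, `score` (aligned so
#'   higher = more malignant), `malignant` (logical), `direction`.
#' @export
labeled_scores <- function(values, labels,
                           direction = c("low_malignant", "high_malignant")) {
  direction <- match.arg(direction)
  mal <- as_malignant(labels)
  if (length(values) != length(mal)) stop("values and labels lengths differ")
  if (anyNA(values) || anyNA(mal)) stop("values/labels must not contain NA")
  if (!any(mal) || all(mal)) stop("both classes must be represented")
  structure(list(values = as.numeric(values),
                 score = if (direction == "low_malignant") -values else values,
                 malignant = mal, direction = direction),
            class = "labeled_scores")
}

as_malignant <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  lab <- tolower(as.character(labels))
  if (!all(lab %in% c("benign", "malignant"))) {
    stop("labels must be logical, 0/1 or benign/malignant")
  }
  lab == "malignant"
}

# Midrank placement values: V10[i] = P-hat(positive i outranks a negative),
# V01[j] = P-hat(a positive outranks negative j); ties count 1/2.
# mean(V10) = mean(V01) = AUC (the normalized Mann-Whitney U statistic).
delong_placements <- function(score, malignant) {
  xp <- score[malignant]
  xn <- score[!malignant]
  cmp <- outer(xp, xn, function(a, b) (a > b) + 0.5 * (a == b))
  list(V10 = rowMeans(cmp), V01 = colMeans(cmp), auc = mean(cmp))
}

# DeLong variance-covariance of the AUCs of one or more markers scored on
# the same subjects: S = S10/m + S01/n with S10, S01 the sample covariance
# matrices of the positive/negative placement values.
delong_auc_cov <- function(score_matrix, malignant) {
  score_matrix <- as.matrix(score_matrix)
  m <- sum(malignant); n <- sum(!malignant)
  if (m < 2 || n < 2) stop("need at least 2 subjects per class")
  pl <- lapply(seq_len(ncol(score_matrix)), function(j) {
    delong_placements(score_matrix[, j], malignant)
  })
  aucs <- vapply(pl, `[[`, 0, "auc")
  V10 <- sapply(pl, `[[`, "V10")
  V01 <- sapply(pl, `[[`, "V01")
  S <- stats::cov(V10) / m + stats::cov(V01) / n
  list(aucs = aucs, cov = as.matrix(S))
}

#' Empirical ROC curve with AUC and DeLong confidence interval
#'
#' Threshold sweep over the observed marker values. The AUC equals the
#' normalized Mann-Whitney U statistic (ties counted one half); its variance
#' is DeLong's placement-value estimator and the 95% CI is the normal
#' approximation truncated to \[0, 1\].
#'
#' @param scores A [labeled_scores()] object.
#' @return List of class `roc_result`: `roc` (data.frame `cutoff` on the
#'   original marker scale, `sens`, `spec`), `auc`, `auc_var`, `ci95`,
#'   `scores`.
#' @export
roc_auc <- function(scores) {
  stopifnot(inherits(scores, "labeled_scores"))
  dl <- delong_auc_cov(scores$score, scores$malignant)
  auc <- dl$aucs[1]
  v <- dl$cov[1, 1]
  ci <- pmin(pmax(auc + c(-1, 1) * 1.96 * sqrt(v), 0), 1)
  cuts <- sort(unique(scores$values))
  sw <- t(vapply(cuts, function(cc) {
    pred <- classify_at(scores$values, cc, scores$direction)
    c(sens = mean(pred[scores$malignant]),
      spec = mean(!pred[!scores$malignant]))
  }, c(sens = 0, spec = 0)))
  structure(list(roc = data.frame(cutoff = cuts, sens = sw[, "sens"],
                                  spec = sw[, "spec"]),
                 auc = auc, auc_var = v, ci95 = ci, scores = scores),
            class = "roc_result")
}

# Classification rule at a cutoff on the original marker scale.
classify_at <- function(values, cutoff, direction) {
  if (direction == "low_malignant") values <= cutoff else values >= cutoff
}

#' Youden-optimal cutoff and its diagnostic metrics
#'
#' Maximizes J = sensitivity + specificity - 1 over all observed cutoff
#' values. Ties are broken toward the cutoff with higher sensitivity, then
#' toward the lower threshold value.
#'
#' @param roc A `roc_result` from [roc_auc()], or a [labeled_scores()].
#' @return List of class `diagnostic_result`: `auc`, `ci95`, `cutoff`,
#'   `youden_j`, `sens`, `spec`, `ppv`, `npv`, `accuracy` (all rates in %),
#'   `counts` (tp, fn, tn, fp), `direction`.
#' @export
youden_optimal <- function(roc) {
  if (inherits(roc, "labeled_scores")) roc <- roc_auc(roc)
  stopifnot(inherits(roc, "roc_result"))
  tab <- roc$roc
  j <- tab$sens + tab$spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[tab$sens[best] == max(tab$sens[best])]
  if (length(best) > 1) best <- best[which.min(tab$cutoff[best])]
  cutoff <- tab$cutoff[best]

  sc <- roc$scores
  pred <- classify_at(sc$values, cutoff, sc$direction)
  tp <- sum(pred & sc$malignant); fn <- sum(!pred & sc$malignant)
  tn <- sum(!pred & !sc$malignant); fp <- sum(pred & !sc$malignant)
  cm <- confusion_metrics(tp, fn, tn, fp)
  structure(list(auc = roc$auc, ci95 = roc$ci95, cutoff = cutoff,
                 youden_j = tab$sens[best] + tab$spec[best] - 1,
                 sens = cm$sens, spec = cm$spec, ppv = cm$ppv, npv = cm$npv,
                 accuracy = cm$accuracy,
                 counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 direction = sc$direction),
            class = "diagnostic_result")
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(sprintf(paste0("AUC %.3f (95%% CI %.3f-%.3f); cutoff %.4g ",
                     "(J = %.3f); sens %.2f%%, spec %.2f%%, acc %.2f%%\n"),
              x$auc, x$ci95[1], x$ci95[2], x$cutoff, x$youden_j,
              x$sens, x$spec, x$accuracy))
  invisible(x)
}

#' Confusion-matrix rates
#'
#' Sensitivity, specificity, PPV, NPV and accuracy as percentages from the
#' four confusion counts. A zero PPV/NPV denominator yields `NA` with an
#' `undefined` flag rather than an error.
#'
#' @param tp,fn,tn,fp Non-negative integer counts; `tp + fn >= 1` and
#'   `tn + fp >= 1`.
#' @return List with `sens`, `spec`, `ppv`, `npv`, `accuracy` (percent) and
#'   `undefined` (character vector naming any undefined rates).
#' @examples
#' confusion_metrics(21, 1, 22, 2)  # sens 95.45, spec 91.67
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  cnt <- c(tp, fn, tn, fp)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop("counts must be non-negative integers")
  }
  if (tp + fn < 1 || tn + fp < 1) stop("each class needs at least one subject")
  undef <- character(0)
  ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else {
    undef <- c(undef, "ppv"); NA_real_
  }
  npv <- if (tn + fn > 0) 100 * tn / (tn + fn) else {
    undef <- c(undef, "npv"); NA_real_
  }
  list(sens = 100 * tp / (tp + fn), spec = 100 * tn / (tn + fp),
       ppv = ppv, npv = npv,
       accuracy = 100 * (tp + tn) / sum(cnt), undefined = undef)
}

#' DeLong z-test for two correlated AUCs
#'
#' Compares the AUCs of two markers measured on the same subjects using the
#' DeLong placement-value covariance: z = (A1 - A2) / sqrt(v1 + v2 - 2 c),
#' two-sided p. Swapping the markers negates z and leaves p unchanged.
#'
#' @param scores1,scores2 [labeled_scores()] on identical subjects/labels.
#' @return List of class `auc_comparison`: `auc1`, `auc2`, `z`, `p_value`,
#'   `cov` (2 x 2 covariance matrix of the AUC estimates).
#' @export
delong_test <- function(scores1, scores2) {
  stopifnot(inherits(scores1, "labeled_scores"),
            inherits(scores2, "labeled_scores"))
  if (!identical(scores1$malignant, scores2$malignant)) {
    stop("the two markers must be scored on identical subjects and labels")
  }
  dl <- delong_auc_cov(cbind(scores1$score, scores2$score),
                       scores1$malignant)
  vd <- dl$cov[1, 1] + dl$cov[2, 2] - 2 * dl$cov[1, 2]
  z <- if (vd <= 0) 0 else (dl$aucs[1] - dl$aucs[2]) / sqrt(vd)
  structure(list(auc1 = dl$aucs[1], auc2 = dl$aucs[2], z = z,
                 p_value = 2 * stats::pnorm(-abs(z)), cov = dl$cov),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("DeLong test: AUC %.3f vs %.3f, z = %.3f, p = %.4f\n",
              x$auc1, x$auc2, x$z, x$p_value))
  invisible(x)
}

#' Logistic combination of diagnostic markers
#'
#' Maximum-likelihood binary logistic regression of malignancy on two or
#' more markers; the combined score is the linear predictor, whose ROC/AUC
#' is computed like any marker's (the ROC is invariant to the monotone
#' logistic link). Perfect separation is flagged as non-convergence rather
#' than silently reported.
#'
#' @param markers Data frame (or named list) of numeric marker columns.
#' @param labels Malignancy labels as in [labeled_scores()].
#' @return List of class `logistic_combination`: `coefficients`, `converged`
#'   (FALSE under perfect separation), `score` (linear predictor),
#'   `scores` ([labeled_scores()] of the combined score), `diag`
#'   (its [youden_optimal()] result), `fit` (the `glm` object).
#' @export
logistic_combine <- function(markers, labels) {
  df <- as.data.frame(markers)
  if (ncol(df) < 1) stop("need at least one marker")
  mal <- as_malignant(labels)
  if (!any(mal) || all(mal)) stop("both classes must be represented")
  df$.y <- as.integer(mal)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  converged <- fit$converged && !sep_warn
  score <- as.numeric(stats::predict(fit, type = "link"))
  sc <- labeled_scores(score, mal, direction = "high_malignant")
  structure(list(coefficients = stats::coef(fit), converged = converged,
                 score = score, scores = sc, diag = youden_optimal(sc),
                 fit = fit),
            class = "logistic_combination")
}
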