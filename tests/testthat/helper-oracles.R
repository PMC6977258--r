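# Independent brute-force oracles used to validate the package's statistics.

# ICC(2,1) via R's aov() two-way ANOVA table (independent route from the
# package's direct sum-of-squares implementation).
oracle_icc21 <- function(x, y) {
  n <- length(x)
  d <- data.frame(v = c(x, y),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(v ~ subj + rater, data = d))[[1]]$`Mean Sq`
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  k <- 2
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# AUC by exhaustive enumeration of positive-negative pairs (ties = 1/2),
# after aligning so that higher score indicates the positive class.
oracle_auc <- function(values, malignant, direction = "low_malignant") {
  s <- if (direction == "low_malignant") -values else values
  pos <- s[malignant]; neg <- s[!malignant]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Jackknife covariance of two AUC estimates: delete-one pseudovalue
# covariance computed separately within each class and summed.
oracle_jackknife_cov <- function(s1, s2, malignant) {
  auc_pair <- function(keep) {
    m <- malignant[keep]
    c(oracle_auc(s1[keep], m, "high_malignant"),
      oracle_auc(s2[keep], m, "high_malignant"))
  }
  jack_group <- function(idx) {
    loo <- t(vapply(idx, function(i) auc_pair(setdiff(seq_along(s1), i)),
                    c(0, 0)))
    ctr <- sweep(loo, 2, colMeans(loo))
    ((length(idx) - 1) / length(idx)) * crossprod(ctr)
  }
  jack_group(which(malignant)) + jack_group(which(!malignant))
}

# Youden cutoff by exhaustive search over observed values with the package's
# documented tie-breaks (higher sensitivity, then lower threshold).
oracle_youden <- function(values, malignant, direction = "low_malignant") {
  cuts <- sort(unique(values))
  best <- NULL
  for (cc in cuts) {
    pred <- if (direction == "low_malignant") values <= cc else values >= cc
    sens <- mean(pred[malignant]); spec <- mean(!pred[!malignant])
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12)) {
      best <- list(cutoff = cc, j = j, sens = sens, spec = spec)
    }
  }
  best
}

# Binary logistic regression by hand-rolled Newton-Raphson (IRLS).
oracle_logistic <- function(X, y, iter = 50) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    step <- solve(t(X) %*% (X * W), t(X) %*% (y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

# Analytic mean of a Rician-distributed magnitude with signal A, noise sigma.
rician_mean <- function(A, sigma) {
  # exp(-x/2) folded into the exponentially scaled Bessel functions
  x <- A^2 / (2 * sigma^2)
  sigma * sqrt(pi / 2) *
    ((1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
       x * besselI(x / 2, 1, expon.scaled = TRUE))
}

# Small helpers to build fixtures in code.
toy_decay <- function(params, S0 = 1000, b = default_b_values()) {
  signal_decay(acquisition_scheme(b), S0 * ivim_signal(params, b))
}

benign_wl_params <- function() ivim_params(1.24e-3, 0.3795, 10.95e-3)
malignant_wl_params <- function() ivim_params(0.69e-3, 0.2936, 11.54e-3)

# A small homogeneous 4D volume with every voxel following `params`.
toy_volume <- function(params, dims = c(4, 4, 2), S0 = 1000,
                       b = default_b_values(), noise_sigma = 0, seed = 1) {
  sig <- array(rep(S0 * ivim_signal(params, b), each = prod(dims)),
               c(dims, length(b)))
  if (noise_sigma > 0) sig <- rician_noise(sig, noise_sigma * S0, seed)
  dwi_volume(sig, b)
}

# A fast, small phantom spec for pipeline-level tests.
small_spec <- function(...) {
  nodule_phantom_spec(grid_dim = c(16, 16, 6), voxel_size = c(1.5, 1.5, 5),
                      semi_axes_mm = c(8, 7, 7.5), ...)
}
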