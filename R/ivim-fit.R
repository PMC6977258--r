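#' Configuration of the IVIM fitter
#'
#' The fitter runs bounded nonlinear least squares on the full bi-exponential
#' model. Starting values come from a segmented estimate: a log-linear fit
#' over the high-b points (b >= `b_split`) yields initial D and f, and the
#' low-b residuals yield an initial D*. All three parameters are then refit
#' jointly, so no b-value cutoff enters the final estimate.
#'
#' @param strategy `"segmented_init_then_full"` (default) or `"full_nlls"`
#'   (fixed generic start, no segmented initialization).
#' @param b_split b-value (s/mm^2) separating the perfusion-dominated low-b
#'   regime from the diffusion-dominated high-b regime used only for
#'   initialization. Must be one of the scheme's b-values.
#' @param multistart Number of random extra starts (>= 1 total starts); the
#'   best residual norm wins. 1 means the segmented start only.
#' @param tolerance Convergence tolerance on the residual sum of squares.
#' @param seed Integer seed for the multistart draws.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(strategy = c("segmented_init_then_full", "full_nlls"),
                       b_split = 200, multistart = 1L, tolerance = 1e-12,
                       seed = 1L) {
  strategy <- match.arg(strategy)
  if (multistart < 1) stop("multistart must be >= 1")
  structure(list(strategy = strategy, b_split = b_split,
                 multistart = as.integer(multistart),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "fit_config")
}

# Segmented starting values on a normalized decay (y = S/S0).
# High-b log-linear fit gives D and (1 - f); low-b residuals give D*.
segmented_start <- function(b, y, b_split) {
  hi <- b >= b_split
  if (sum(hi) < 2) hi <- b >= stats::median(b)
  cf <- stats::lm.fit(cbind(1, -b[hi]), log(y[hi]))$coefficients
  D0 <- min(max(cf[2], 1.1e-7), 9.9e-3)
  f0 <- min(max(1 - exp(cf[1]), 1e-3), 0.95)
  lo <- !hi & b > 0
  resid <- y[lo] - (1 - f0) * exp(-b[lo] * D0)
  ok <- resid > 0
  Dstar0 <- 10e-3
  if (sum(ok) >= 2) {
    cf2 <- stats::lm.fit(cbind(1, -b[lo][ok]), log(resid[ok]))$coefficients
    if (is.finite(cf2[2]) && cf2[2] > D0) Dstar0 <- min(cf2[2], 0.09)
  }
  c(D = D0, f = f0, delta = max(Dstar0 - D0, 1e-6))
}

# One bounded Levenberg-Marquardt run; par = (D, f, delta) with
# D* = D + delta, which encodes the D* > D constraint as a box.
run_nlls <- function(b, y, start, tolerance) {
  lower <- c(ivim_bounds()$D_min, 0, 1e-7)
  upper <- c(ivim_bounds()$D_max - 1e-9, 1,
             ivim_bounds()$D_star_max - ivim_bounds()$D_max)
  start <- pmin(pmax(start, lower), upper)
  fit <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper,
    fn = function(p) (1 - p[2]) * exp(-b * p[1]) + p[2] * exp(-b * (p[1] + p[3])) - y,
    control = minpack.lm::nls.lm.control(ftol = tolerance, ptol = tolerance,
                                         maxiter = 200))
  list(par = fit$par, rss = fit$deviance,
       converged = fit$info %in% 1:4)
}

#' Fit the constrained bi-exponential IVIM model to a signal decay
#'
#' Fits Sb/S0 = (1 - f) exp(-b D) + f exp(-b D*) by bounded nonlinear least
#' squares under the constraints 0 < D < 0.01 mm^2/s, D < D* <= 0.1 mm^2/s,
#' f in \[0, 1\]. S0 is taken from the b = 0 measurement, not fitted.
#'
#' @param decay A [signal_decay()] with at least 4 distinct b-values.
#' @param config A [fit_config()].
#' @return List of class `ivim_fit` with elements `params` ([ivim_params()]),
#'   `rss` (residual sum of squares on the normalized decay), `converged`
#'   (logical; non-convergence is flagged, never silently NA), and `n_b`.
#' @examples
#' p <- ivim_params(1.24e-3, 0.3795, 10.95e-3)
#' d <- signal_decay(acquisition_scheme(), 1000 * ivim_signal(p, default_b_values()))
#' fit_ivim(d)$params
#' @export
fit_ivim <- function(decay, config = fit_config()) {
  if (!inherits(decay, "signal_decay")) stop("decay must be a signal_decay")
  b <- decay$b
  if (length(unique(b)) < 4) stop("need >= 4 distinct b-values to fit IVIM")
  y <- decay$S / decay$S[1]

  starts <- list()
  if (config$strategy == "segmented_init_then_full") {
    starts[[1]] <- segmented_start(b, y, config$b_split)
  } else {
    starts[[1]] <- c(D = 1e-3, f = 0.2, delta = 9e-3)
  }
  if (config$multistart > 1) {
    rs <- local_rng(config$seed, {
      replicate(config$multistart - 1L,
                c(D = stats::runif(1, 1e-4, 9e-3),
                  f = stats::runif(1, 0.01, 0.8),
                  delta = stats::runif(1, 1e-3, 5e-2)),
                simplify = FALSE)
    })
    starts <- c(starts, rs)
  }

  best <- NULL
  for (s in starts) {
    fit <- run_nlls(b, y, s, config$tolerance)
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  p <- best$par
  structure(list(
    params = ivim_params(D = p[1], f = p[2], D_star = p[1] + p[3]),
    rss = best$rss, converged = best$converged, n_b = length(b)),
    class = "ivim_fit")
}

#' Two-point mono-exponential ADC
#'
#' Inverts ln(Sb) = ln(S0) - b ADC using the b = 0 point and one high
#' b-value: ADC = ln(S0 / Sb) / b. The conventional pairs are (0, 600) and
#' (0, 990) s/mm^2, labelled ADC600 and ADC990.
#'
#' @param decay A [signal_decay()].
#' @param b_high The non-zero b-value of the pair; must be in the scheme.
#' @return List of class `adc_result` with `adc` (mm^2/s) and `b_pair`.
#' @examples
#' d <- signal_decay(acquisition_scheme(), 1000 * exp(-default_b_values() * 1.5e-3))
#' fit_adc_two_point(d, 600)$adc   # 1.5e-3
#' @export
fit_adc_two_point <- function(decay, b_high) {
  if (!inherits(decay, "signal_decay")) stop("decay must be a signal_decay")
  if (length(b_high) != 1 || b_high <= 0) stop("b_high must be a single positive b-value")
  idx <- match(b_high, decay$b)
  if (is.na(idx)) stop("b_high = ", b_high, " is not in the acquisition scheme")
  adc <- log(decay$S[1] / decay$S[idx]) / b_high
  structure(list(adc = adc, b_pair = c(0, b_high)), class = "adc_result")
}

#' Voxelwise IVIM parameter maps over a mask
#'
#' Fits the constrained bi-exponential model independently in every masked
#' voxel of a 4D multi-b-value volume. Unmasked voxels carry `NA`.
#'
#' @param volume A [dwi_volume()].
#' @param mask A logical/0-1 3D array (or [roi_mask()]) on the volume grid.
#' @param config A [fit_config()].
#' @return List of class `ivim_maps` with 3D arrays `D`, `f`, `D_star`
#'   (internal units), `rss`, logical `converged`, and the `mask` used.
#' @export
fit_ivim_map <- function(volume, mask, config = fit_config()) {
  stopifnot(inherits(volume, "dwi_volume"))
  m <- as_mask_array(mask, dim(volume$data)[1:3])
  idx <- which(m)
  if (length(idx) == 0) stop("mask is empty")
  dims <- dim(volume$data)[1:3]
  nb <- length(volume$b)
  sig <- matrix(volume$data, ncol = nb)[idx, , drop = FALSE]
  if (any(sig <= 0)) stop("non-positive signal inside mask; cannot fit")

  D <- f <- Ds <- rss <- array(NA_real_, dims)
  conv <- array(NA, dims)
  for (k in seq_along(idx)) {
    d <- signal_decay(volume$b, sig[k, ])
    fit <- fit_ivim(d, config)
    i <- idx[k]
    D[i] <- fit$params$D; f[i] <- fit$params$f; Ds[i] <- fit$params$D_star
    rss[i] <- fit$rss; conv[i] <- fit$converged
  }
  structure(list(D = D, f = f, D_star = Ds, rss = rss, converged = conv,
                 mask = m),
            class = "ivim_maps")
}

#' Voxelwise two-point ADC map over a mask
#'
#' @inheritParams fit_ivim_map
#' @param b_high Non-zero b-value of the (0, b) pair.
#' @return 3D array of ADC values (mm^2/s), `NA` outside the mask.
#' @export
fit_adc_map <- function(volume, mask, b_high) {
  stopifnot(inherits(volume, "dwi_volume"))
  m <- as_mask_array(mask, dim(volume$data)[1:3])
  if (!any(m)) stop("mask is empty")
  idx <- match(b_high, volume$b)
  if (is.na(idx)) stop("b_high = ", b_high, " is not in the acquisition scheme")
  S0 <- volume$data[, , , 1]
  Sb <- volume$data[, , , idx]
  if (any(Sb[m] <= 0) || any(S0[m] <= 0)) stop("non-positive signal inside mask")
  adc <- array(NA_real_, dim(m))
  adc[m] <- log(S0[m] / Sb[m]) / b_high
  adc
}
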