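#' Labelled region-of-interest mask
#'
#' A binary 3D mask on the volume grid, tagged with its delineation method
#' (whole-lesion `"W-L"` or single-section `"S-S"`), observer and session.
#' S-S masks must occupy exactly one slice and contain 20-60 pixels; W-L
#' masks may span multiple slices.
#'
#' @param mask Logical (or 0/1) 3D array.
#' @param method `"W-L"` or `"S-S"`.
#' @param observer,session Integer ids.
#' @param roi_index For S-S masks, which of the delineation's two ROIs this
#'   is (1 or 2); `NA` for W-L.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, method = c("W-L", "S-S"), observer = 1L,
                     session = 1L, roi_index = NA_integer_) {
  method <- match.arg(method)
  if (is.null(dim(mask)) || length(dim(mask)) != 3) {
    stop("mask must be a 3D array")
  }
  m <- array(as.logical(mask), dim(mask))
  n <- sum(m)
  if (n == 0) stop("ROI mask is empty")
  slices <- which(apply(m, 3, any))
  if (method == "S-S") {
    if (length(slices) != 1) stop("an S-S mask must occupy exactly one slice")
    if (n < 20 || n > 60) {
      stop("an S-S mask must contain 20-60 pixels, got ", n)
    }
  }
  structure(list(mask = m, method = method, observer = as.integer(observer),
                 session = as.integer(session),
                 roi_index = as.integer(roi_index), slices = slices,
                 n_voxels = n),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("%s ROI (observer %d, session %d%s): %d voxels on slice(s) %s\n",
              x$method, x$observer, x$session,
              if (!is.na(x$roi_index)) paste0(", roi ", x$roi_index) else "",
              x$n_voxels, paste(x$slices, collapse = ",")))
  invisible(x)
}

#' Mean parameter values over an ROI
#'
#' Arithmetic mean of each voxelwise map over the masked voxels, excluding
#' missing-value (`NA`) voxels. The aggregate is permutation-invariant and
#' bounded by the masked voxels' min and max.
#'
#' @param maps An `ivim_maps` object from [fit_ivim_map()], or a named list
#'   of 3D arrays.
#' @param mask An [roi_mask()] or logical 3D array on the same grid.
#' @return Named list of ROI means (one per map) plus `n_voxels`, the count
#'   of masked non-missing voxels used.
#' @export
summarize_roi <- function(maps, mask) {
  arrays <- if (inherits(maps, "ivim_maps")) {
    maps[c("D", "f", "D_star")]
  } else {
    maps
  }
  stopifnot(is.list(arrays), length(arrays) >= 1)
  m <- as_mask_array(mask, dim(arrays[[1]]))
  out <- lapply(arrays, function(a) {
    v <- a[m]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    mean(v)
  })
  if (all(vapply(out, is.na, TRUE))) {
    stop("ROI contains no fitted (non-missing) voxels")
  }
  out$n_voxels <- sum(m & !is.na(arrays[[1]]))
  out
}

#' Combine the two single-section ROI measurements of one nodule
#'
#' The study protocol measures two S-S ROIs per nodule per session; they are
#' combined into one value per parameter, by default as the unweighted mean
#' of the two ROI means, optionally weighted by ROI pixel count.
#'
#' @param m1,m2 ROI summaries (named lists as returned by [summarize_roi()],
#'   each including `n_voxels`).
#' @param weighting `"unweighted"` (default) or `"pixel"`.
#' @return Named list of combined values (same names as the inputs minus
#'   `n_voxels`), plus `n_voxels` = total pixel count.
#' @export
aggregate_ss <- function(m1, m2, weighting = c("unweighted", "pixel")) {
  weighting <- match.arg(weighting)
  if (missing(m2)) stop("exactly two S-S ROI measurements are required")
  keys <- setdiff(intersect(names(m1), names(m2)), "n_voxels")
  if (length(keys) == 0) stop("no common parameters to aggregate")
  w <- if (weighting == "pixel") {
    c(m1$n_voxels, m2$n_voxels) / (m1$n_voxels + m2$n_voxels)
  } else {
    c(0.5, 0.5)
  }
  out <- lapply(keys, function(k) w[1] * m1[[k]] + w[2] * m2[[k]])
  names(out) <- keys
  out$n_voxels <- (m1$n_voxels %||% NA) + (m2$n_voxels %||% NA)
  out
}

#' Fit an ROI by voxelwise-then-average or average-then-fit
#'
#' Two readings of "ROI parameter value" coexist in the field: fit every
#' voxel and average the parameter maps over the ROI (`fit_then_average`),
#' or average the raw signal over the ROI at each b-value and fit that
#' single mean decay (`average_then_fit`). Both are provided; on a
#' homogeneous noiseless ROI they agree, and on heterogeneous ROIs their
#' difference is the Jensen gap of the nonlinear model.
#'
#' @param volume A [dwi_volume()].
#' @param mask An [roi_mask()] or logical 3D array.
#' @param config A [fit_config()].
#' @param mode `"fit_then_average"` or `"average_then_fit"`.
#' @return Named list with `D`, `f`, `D_star` (internal units), `mode`, and
#'   `n_voxels`.
#' @export
roi_fit_mode <- function(volume, mask, config = fit_config(),
                         mode = c("fit_then_average", "average_then_fit")) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "dwi_volume"))
  m <- as_mask_array(mask, dim(volume$data)[1:3])
  if (!any(m)) stop("mask is empty")
  if (mode == "fit_then_average") {
    maps <- fit_ivim_map(volume, m, config)
    s <- summarize_roi(maps, m)
    return(list(D = s$D, f = s$f, D_star = s$D_star, mode = mode,
                n_voxels = s$n_voxels))
  }
  nb <- length(volume$b)
  sig <- matrix(volume$data, ncol = nb)[which(m), , drop = FALSE]
  mean_sig <- colMeans(sig)
  fit <- fit_ivim(signal_decay(volume$b, mean_sig), config)
  list(D = fit$params$D, f = fit$params$f, D_star = fit$params$D_star,
       mode = mode, n_voxels = sum(m))
}
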