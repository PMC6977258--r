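#' Observer delineation model
#'
#' Describes how simulated readers deviate from the true nodule boundary.
#' Whole-lesion (W-L) masks are perturbed by per-slice morphological
#' dilation/erosion with a random radius up to `boundary_jitter` mm.
#' Single-section (S-S) masks are round/oval ROIs of 20-60 pixels placed in
#' the solid compartment of two observer-chosen tumour-containing slices;
#' slice choice, position, size and shape are redrawn independently per
#' observer and session.
#'
#' @param boundary_jitter W-L boundary perturbation scale, mm (0 disables).
#' @param ss_size_range Pixel-count range of one S-S ROI; must lie within
#'   \[20, 60\].
#' @param ss_min_solid Minimum number of solid voxels a slice must contain to
#'   be eligible for S-S placement.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(boundary_jitter = 1.5, ss_size_range = c(20, 60),
                           ss_min_solid = 40) {
  if (ss_size_range[1] < 20 || ss_size_range[2] > 60 ||
      ss_size_range[1] > ss_size_range[2]) {
    stop("ss_size_range must lie within [20, 60]")
  }
  if (boundary_jitter < 0) stop("boundary_jitter must be >= 0")
  structure(list(boundary_jitter = boundary_jitter,
                 ss_size_range = as.integer(ss_size_range),
                 ss_min_solid = ss_min_solid),
            class = "observer_model")
}

# 2D morphological dilation (radius > 0) or erosion (radius < 0) of a
# logical matrix by a disk of |radius| pixels.
morph_disk <- function(m, radius) {
  if (radius == 0) return(m)
  r <- abs(radius)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= r^2 + 1e-9, ]
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(if (radius > 0) FALSE else TRUE, nr, nc)
  for (k in seq_len(nrow(off))) {
    sh <- shift_mat(m, off$dx[k], off$dy[k], fill = radius < 0)
    acc <- if (radius > 0) acc | sh else acc & sh
  }
  acc
}

shift_mat <- function(m, dx, dy, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  xs <- seq_len(nr) - dx; ys <- seq_len(nc) - dy
  okx <- xs >= 1 & xs <= nr; oky <- ys >= 1 & ys <= nc
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

# Jitter a 3D mask slice by slice: each tumour-containing slice gets an
# independent integer dilation/erosion radius in [-jr, jr]. A radius that
# would empty a non-empty slice is redrawn; after 10 attempts the slice is
# kept unperturbed (never silently dropped).
jitter_mask <- function(mask, jitter_vox) {
  jr <- round(jitter_vox)
  if (jr <= 0) return(mask)
  out <- mask
  for (z in seq_len(dim(mask)[3])) {
    sl <- mask[, , z]
    if (!any(sl)) next
    for (attempt in 1:10) {
      r <- sample(-jr:jr, 1)
      new_sl <- morph_disk(sl, r)
      if (any(new_sl)) break
      new_sl <- sl
    }
    out[, , z] <- new_sl
  }
  out
}

# Place one round/oval S-S ROI of n_px pixels in the solid part of slice z:
# an ellipse with random orientation/aspect grown around a random solid
# center, intersected with the solid mask; nearest-to-center pixels keep the
# count exact.
place_ss_roi <- function(solid_slice, n_px, max_tries = 25) {
  cand <- which(solid_slice, arr.ind = TRUE)
  nr <- nrow(solid_slice); nc <- ncol(solid_slice)
  for (try in seq_len(max_tries)) {
    c_idx <- cand[sample.int(nrow(cand), 1), ]
    aspect <- stats::runif(1, 1, 1.6)
    theta <- stats::runif(1, 0, pi)
    # semi-axes so the ellipse area ~ 1.6 * n_px, leaving room to trim back
    a <- sqrt(1.6 * n_px * aspect / pi)
    b <- a / aspect
    xs <- matrix(seq_len(nr) - c_idx[1], nr, nc)
    ys <- matrix(rep(seq_len(nc) - c_idx[2], each = nr), nr, nc)
    u <- xs * cos(theta) + ys * sin(theta)
    v <- -xs * sin(theta) + ys * cos(theta)
    metric <- (u / a)^2 + (v / b)^2
    sel <- metric <= 1 & solid_slice
    if (sum(sel) >= n_px) {
      keep <- which(sel)
      keep <- keep[order(metric[sel])][seq_len(n_px)]
      roi <- matrix(FALSE, nr, nc)
      roi[keep] <- TRUE
      return(roi)
    }
  }
  # fallback: the n_px solid pixels nearest a random solid center (a compact
  # roughly-round blob), used when no ellipse of the drawn shape fits
  if (nrow(cand) >= n_px) {
    c_idx <- cand[sample.int(nrow(cand), 1), ]
    d2 <- (cand[, 1] - c_idx[1])^2 + (cand[, 2] - c_idx[2])^2
    keep <- cand[order(d2)[seq_len(n_px)], , drop = FALSE]
    roi <- matrix(FALSE, nr, nc)
    roi[keep] <- TRUE
    return(roi)
  }
  NULL
}

#' Simulate observer- and session-specific ROI delineations of a phantom
#'
#' For every (observer, session) pair, produces one jittered whole-lesion
#' 3D mask and two single-section ROIs placed in the solid compartment of
#' two distinct tumour-containing slices.
#'
#' @param nodule A `nodule_phantom` from [generate_nodule()].
#' @param model An [observer_model()].
#' @param n_observers,n_sessions Numbers of readers and repeat sessions.
#' @param seed Integer seed.
#' @return List of [roi_mask()] objects; W-L masks have `roi_index = NA`,
#'   the two S-S ROIs of a delineation have `roi_index` 1 and 2.
#' @export
simulate_observer_masks <- function(nodule, model = observer_model(),
                                    n_observers = 2, n_sessions = 2,
                                    seed = 1) {
  stopifnot(inherits(nodule, "nodule_phantom"),
            inherits(model, "observer_model"))
  if (!any(nodule$true_mask)) stop("true mask is empty")
  jitter_vox <- model$boundary_jitter / nodule$spec$voxel_size[1]
  masks <- list()
  for (obs in seq_len(n_observers)) {
    for (ses in seq_len(n_sessions)) {
      masks_os <- local_rng(sub_seed(seed, obs * 37 + ses), {
        wl <- jitter_mask(nodule$true_mask, jitter_vox)
        if (!any(wl)) stop("observer jitter produced an empty W-L mask")
        out <- list(roi_mask(wl, method = "W-L", observer = obs,
                             session = ses))
        solid_counts <- apply(nodule$solid_mask, 3, sum)
        elig <- which(solid_counts >= model$ss_min_solid)
        if (length(elig) < 2) {
          elig <- order(solid_counts, decreasing = TRUE)[1:2]
          if (solid_counts[elig[2]] < max(20, 1)) {
            stop("fewer than two tumour-containing slices for S-S placement")
          }
        }
        zs <- if (length(elig) == 2) elig else sample(elig, 2)
        for (k in 1:2) {
          n_px <- sample(model$ss_size_range[1]:model$ss_size_range[2], 1)
          n_px <- max(min(n_px, solid_counts[zs[k]]),
                      model$ss_size_range[1])
          roi2d <- place_ss_roi(nodule$solid_mask[, , zs[k]], n_px)
          if (is.null(roi2d)) {
            stop("could not place an S-S ROI of ", n_px,
                 " pixels on slice ", zs[k])
          }
          m3 <- array(FALSE, dim(nodule$true_mask))
          m3[, , zs[k]] <- roi2d
          out[[k + 1]] <- roi_mask(m3, method = "S-S", observer = obs,
                                   session = ses, roi_index = k)
        }
        out
      })
      masks <- c(masks, masks_os)
    }
  }
  masks
}
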