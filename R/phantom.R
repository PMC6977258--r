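#' Group-level IVIM parameter distributions
#'
#' Mean and standard deviation of D, f and D* on the conventional reporting
#' scale (x10^-3 mm^2/s, %, x10^-3 mm^2/s), describing how whole-lesion mean
#' parameters vary across nodules of one diagnostic group. Per-nodule values
#' are drawn from independent normals truncated to the fitting bounds.
#'
#' @param name Group label, `"benign"` or `"malignant"`.
#' @param D_mean,D_sd Mean/SD of D, x10^-3 mm^2/s.
#' @param f_mean,f_sd Mean/SD of f, %.
#' @param D_star_mean,D_star_sd Mean/SD of D*, x10^-3 mm^2/s.
#' @return An object of class `group_distribution`.
#' @export
group_distribution <- function(name, D_mean, D_sd, f_mean, f_sd,
                               D_star_mean, D_star_sd) {
  stopifnot(is.character(name), D_sd >= 0, f_sd >= 0, D_star_sd >= 0)
  structure(list(name = name,
                 D = c(mean = D_mean, sd = D_sd),
                 f = c(mean = f_mean, sd = f_sd),
                 D_star = c(mean = D_star_mean, sd = D_star_sd)),
            class = "group_distribution")
}

#' Default benign / malignant thyroid nodule group distributions
#'
#' Whole-lesion group means and SDs of the thyroid-nodule cohort the phantom
#' emulates: benign D 1.24 +/- 0.35, f 37.95 +/- 10.05 %, D* 10.95 +/- 2.55;
#' malignant D 0.69 +/- 0.13, f 29.36 +/- 5.69 %, D* 11.54 +/- 1.87
#' (D and D* in x10^-3 mm^2/s).
#'
#' @return Named list with `benign` and `malignant` [group_distribution()]s.
#' @export
thyroid_group_defaults <- function() {
  list(
    benign = group_distribution("benign", 1.24, 0.35, 37.95, 10.05,
                                10.95, 2.55),
    malignant = group_distribution("malignant", 0.69, 0.13, 29.36, 5.69,
                                   11.54, 1.87)
  )
}

# Normal draw truncated to [lo, hi] by rejection (bounds are several SDs
# from the defaults' means, so rejection is cheap).
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Draw per-nodule mean IVIM parameters from a group distribution
#'
#' Independent truncated normal draws on the reporting scale, converted to
#' internal units. Truncation: D in (0, 10), D* in (0.2, 100) x10^-3 mm^2/s,
#' f in (0, 100) %, and D* > D enforced by redrawing D*.
#'
#' @param n Number of nodules.
#' @param group A [group_distribution()].
#' @param seed Integer seed.
#' @return List of `n` [ivim_params()] objects.
#' @export
sample_group_params <- function(n, group, seed) {
  stopifnot(inherits(group, "group_distribution"), n >= 1)
  local_rng(seed, {
    D <- rtruncnorm1(n, group$D["mean"], group$D["sd"], 1e-3, 9.99)
    f <- rtruncnorm1(n, group$f["mean"], group$f["sd"], 1e-2, 99.9)
    Ds <- numeric(n)
    for (i in seq_len(n)) {
      Ds[i] <- rtruncnorm1(1, group$D_star["mean"], group$D_star["sd"],
                           D[i] + 0.2, 99.9)
    }
    lapply(seq_len(n), function(i) {
      ivim_params(D = D[i] * 1e-3, f = f[i] / 100, D_star = Ds[i] * 1e-3)
    })
  })
}

#' Specification of a synthetic nodule DWI phantom
#'
#' Describes the imaging grid, the ellipsoidal nodule geometry, the optional
#' cystic/necrotic subregion, the spatially correlated within-nodule
#' parameter texture, the surrounding parenchyma, and the Rician noise level.
#'
#' @param grid_dim Integer length-3 grid size (voxels).
#' @param voxel_size Voxel edge lengths, mm.
#' @param semi_axes_mm Ellipsoid semi-axes of the nodule, mm.
#' @param cystic_fraction Proportion of nodule volume assigned cystic
#'   parameters, in \[0, 1).
#' @param cyst_params [ivim_params()] of the cystic compartment (free-water
#'   like: high D, low f).
#' @param background_params [ivim_params()] of the surrounding parenchyma.
#' @param S0 Signal level at b = 0, arbitrary units.
#' @param noise_sigma Rician noise scale as a fraction of `S0`
#'   (0.025 = SNR 40 at b = 0); 0 disables noise.
#' @param texture_sd Named numeric: voxelwise SD of the within-nodule
#'   parameter texture for `D`, `f`, `D_star`, internal units.
#' @param texture_corr_vox Gaussian correlation length of the texture field
#'   per axis, voxels; 0 gives independent voxels.
#' @return An object of class `nodule_phantom_spec`.
#' @export
nodule_phantom_spec <- function(grid_dim = c(32, 32, 8),
                                voxel_size = c(1.5, 1.5, 5),
                                semi_axes_mm = c(13, 10, 8),
                                cystic_fraction = 0.05,
                                cyst_params = ivim_params(2.8e-3, 0.05, 12e-3),
                                background_params = ivim_params(1.4e-3, 0.25, 9e-3),
                                S0 = 1000,
                                noise_sigma = 0.01,
                                texture_sd = c(D = 0.35e-3, f = 0.10,
                                               D_star = 4e-3),
                                texture_corr_vox = c(2.5, 2.5, 0.7)) {
  if (cystic_fraction < 0 || cystic_fraction >= 1) {
    stop("cystic_fraction must lie in [0, 1)")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (any(semi_axes_mm <= 0)) stop("semi-axes must be positive")
  radii_vox <- semi_axes_mm / voxel_size
  if (any(2 * radii_vox + 2 > grid_dim)) {
    stop("nodule does not fit inside the grid")
  }
  validate_ivim_params(cyst_params)
  validate_ivim_params(background_params)
  structure(list(grid_dim = as.integer(grid_dim), voxel_size = voxel_size,
                 semi_axes_mm = semi_axes_mm,
                 cystic_fraction = cystic_fraction,
                 cyst_params = cyst_params,
                 background_params = background_params, S0 = S0,
                 noise_sigma = noise_sigma, texture_sd = texture_sd,
                 texture_corr_vox = texture_corr_vox),
            class = "nodule_phantom_spec")
}

# Separable 3D Gaussian smoothing with reflecting edges; sigma in voxels.
gauss_smooth3 <- function(arr, sigma) {
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    arr <- apply_along(arr, ax, function(v) {
      n <- length(v)
      pad <- c(v[pmin(half:1, n)], v, v[pmax(n - (1:half) + 1, 1)])
      stats::convolve(pad, rev(k), type = "filter")
    })
  }
  arr
}

# Apply a length-preserving function along axis `ax` of a 3D array.
apply_along <- function(arr, ax, fn) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(arr, perm), nrow = d[ax])
  m <- apply(m, 2, fn)
  aperm(array(m, d[perm]), order(perm))
}

# Zero-mean, unit-SD spatially correlated Gaussian field on the grid.
correlated_field <- function(grid_dim, corr_vox) {
  w <- array(stats::rnorm(prod(grid_dim)), grid_dim)
  if (all(corr_vox <= 0)) return(w)
  sm <- gauss_smooth3(w, corr_vox)
  sm / stats::sd(sm)
}

#' Apply Rician noise to magnitude signals
#'
#' Magnitude-MRI noise: |S + n1 + i n2| with n1, n2 ~ N(0, sigma).
#'
#' @param signal Numeric array of noiseless magnitudes.
#' @param sigma Gaussian channel SD (same units as `signal`).
#' @param seed Integer seed.
#' @return Array of noisy magnitudes, same shape.
#' @export
rician_noise <- function(signal, sigma, seed) {
  if (sigma == 0) return(signal)
  local_rng(seed, {
    n <- length(signal)
    re <- signal + stats::rnorm(n, 0, sigma)
    im <- stats::rnorm(n, 0, sigma)
    array(sqrt(re^2 + im^2), dim(signal) %||% n)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate one synthetic nodule DWI phantom
#'
#' Builds an ellipsoidal nodule in a parenchyma background, assigns every
#' voxel true IVIM parameters (solid compartment mean + spatially correlated
#' texture; an optional contiguous cystic subregion with its own parameters),
#' synthesizes the noiseless multi-b-value signal from the bi-exponential
#' model, and applies Rician noise. Identical seeds give bit-identical
#' output.
#'
#' @param spec A [nodule_phantom_spec()].
#' @param params Solid-compartment mean parameters: an [ivim_params()], or a
#'   [group_distribution()] from which one mean triple is drawn.
#' @param seed Integer seed.
#' @param b_values Acquisition scheme b-values.
#' @return List of class `nodule_phantom`: `volume` ([dwi_volume()]),
#'   `true_mask` (logical 3D nodule mask), `solid_mask`, `cyst_mask`,
#'   `true_params` (list of 3D arrays `D`, `f`, `D_star`),
#'   `solid_params` (the generating [ivim_params()]), `spec`, `seed`.
#' @export
generate_nodule <- function(spec, params, seed,
                            b_values = default_b_values()) {
  stopifnot(inherits(spec, "nodule_phantom_spec"))
  if (inherits(params, "group_distribution")) {
    params <- sample_group_params(1, params, sub_seed(seed, 101))[[1]]
  }
  validate_ivim_params(params)
  gd <- spec$grid_dim
  ctr <- (gd + 1) / 2
  rad <- spec$semi_axes_mm / spec$voxel_size

  ix <- array(rep(seq_len(gd[1]), times = gd[2] * gd[3]), gd)
  iy <- array(rep(rep(seq_len(gd[2]), each = gd[1]), times = gd[3]), gd)
  iz <- array(rep(seq_len(gd[3]), each = gd[1] * gd[2]), gd)
  dist2 <- ((ix - ctr[1]) / rad[1])^2 + ((iy - ctr[2]) / rad[2])^2 +
    ((iz - ctr[3]) / rad[3])^2
  nodule <- dist2 <= 1
  if (!any(nodule)) stop("degenerate geometry: empty nodule")

  # cystic subregion: the cystic_fraction of nodule voxels nearest to a
  # randomly placed interior focus (an eccentric blob, as in necrosis)
  cyst <- array(FALSE, gd)
  if (spec$cystic_fraction > 0) {
    n_cyst <- round(spec$cystic_fraction * sum(nodule))
    if (n_cyst > 0) {
      focus <- local_rng(sub_seed(seed, 1), {
        inside <- which(nodule & dist2 <= 0.5)
        inside[sample.int(length(inside), 1)]
      })
      fx <- c(ix[focus], iy[focus], iz[focus])
      d2f <- ((ix - fx[1]) * spec$voxel_size[1])^2 +
        ((iy - fx[2]) * spec$voxel_size[2])^2 +
        ((iz - fx[3]) * spec$voxel_size[3])^2
      ord <- order(d2f[nodule])
      idx_nod <- which(nodule)
      cyst[idx_nod[ord[seq_len(n_cyst)]]] <- TRUE
    }
  }
  solid <- nodule & !cyst

  base <- list(D = array(spec$background_params$D, gd),
               f = array(spec$background_params$f, gd),
               D_star = array(spec$background_params$D_star, gd))
  base$D[solid] <- params$D
  base$f[solid] <- params$f
  base$D_star[solid] <- params$D_star
  base$D[cyst] <- spec$cyst_params$D
  base$f[cyst] <- spec$cyst_params$f
  base$D_star[cyst] <- spec$cyst_params$D_star

  # spatially correlated within-tissue texture, truncated to fit bounds;
  # each field is re-centred over the nodule so that the drawn parameters
  # are exactly the nodule-mean true parameters (texture is within-nodule
  # variation only, not a random shift of the nodule mean)
  tex_seed <- sub_seed(seed, 2)
  fields <- local_rng(tex_seed, {
    lapply(1:3, function(i) {
      fld <- correlated_field(gd, spec$texture_corr_vox)
      fld - mean(fld[nodule])
    })
  })
  bb <- ivim_bounds()
  D <- pmin(pmax(base$D + spec$texture_sd[["D"]] * fields[[1]],
                 2e-5), bb$D_max - 1e-5)
  f <- pmin(pmax(base$f + spec$texture_sd[["f"]] * fields[[2]], 0.005), 0.995)
  Ds <- pmin(pmax(base$D_star + spec$texture_sd[["D_star"]] * fields[[3]],
                  D + 1e-4), bb$D_star_max - 1e-4)

  b <- as.numeric(acquisition_scheme(b_values))
  sig <- (1 - c(f)) * exp(-outer(c(D), b)) + c(f) * exp(-outer(c(Ds), b))
  sig <- spec$S0 * sig
  if (spec$noise_sigma > 0) {
    sig <- rician_noise(sig, spec$noise_sigma * spec$S0, sub_seed(seed, 3))
  }
  vol <- dwi_volume(array(sig, c(gd, length(b))), b, spec$voxel_size)

  structure(list(volume = vol, true_mask = nodule, solid_mask = solid,
                 cyst_mask = cyst,
                 true_params = list(D = D, f = f, D_star = Ds),
                 solid_params = params, spec = spec, seed = seed),
            class = "nodule_phantom")
}

#' Generate a labelled cohort of nodule phantoms
#'
#' Draws per-nodule solid-compartment mean parameters from the benign and
#' malignant group distributions and builds one phantom per nodule. The
#' default cohort size is 24 benign and 22 malignant nodules.
#'
#' @param n_benign,n_malignant Group sizes (each >= 1).
#' @param spec A [nodule_phantom_spec()] template shared by all nodules.
#' @param seed Integer seed.
#' @param groups Named list with `benign` and `malignant`
#'   [group_distribution()]s.
#' @param b_values Acquisition scheme b-values.
#' @return List of class `nodule_cohort`: `nodules` (list of
#'   `nodule_phantom`), `labels` (factor benign/malignant), `manifest`
#'   (data.frame: nodule_id, group, true D/f/D* means on the reporting
#'   scale), `seed`.
#' @export
generate_cohort <- function(n_benign = 24, n_malignant = 22,
                            spec = nodule_phantom_spec(), seed = 1,
                            groups = thyroid_group_defaults(),
                            b_values = default_b_values()) {
  if (n_benign < 1 || n_malignant < 1) {
    stop("both group sizes must be >= 1")
  }
  pb <- sample_group_params(n_benign, groups$benign, sub_seed(seed, 11))
  pm <- sample_group_params(n_malignant, groups$malignant, sub_seed(seed, 12))
  all_params <- c(pb, pm)
  labels <- factor(rep(c("benign", "malignant"), c(n_benign, n_malignant)),
                   levels = c("benign", "malignant"))
  nodules <- lapply(seq_along(all_params), function(i) {
    generate_nodule(spec, all_params[[i]], sub_seed(seed, 1000 + i),
                    b_values = b_values)
  })
  manifest <- data.frame(
    nodule_id = seq_along(all_params),
    group = as.character(labels),
    true_D = vapply(all_params, function(p) p$D * 1e3, 0),
    true_f = vapply(all_params, function(p) p$f * 1e2, 0),
    true_D_star = vapply(all_params, function(p) p$D_star * 1e3, 0))
  structure(list(nodules = nodules, labels = labels, manifest = manifest,
                 seed = seed),
            class = "nodule_cohort")
}
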