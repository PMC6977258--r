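#' 4D multi-b-value DWI volume
#'
#' A 4D signal array indexed (x, y, z, b) together with its voxel size (mm)
#' and acquisition scheme. The 4th dimension follows the scheme's ascending
#' b order; constructors reorder the data if b-values arrive unsorted.
#'
#' @param data 4D numeric array, 4th dimension matching `b_values`.
#' @param b_values Numeric vector of b-values (one per 4th-dim slab).
#' @param voxel_size Numeric length-3, voxel edge lengths in mm.
#' @return An object of class `dwi_volume` with elements `data`, `b`
#'   (an [acquisition_scheme()]) and `voxel_size`.
#' @export
dwi_volume <- function(data, b_values, voxel_size = c(1.5, 1.5, 5)) {
  if (length(dim(data)) != 4) stop("data must be a 4D array (x, y, z, b)")
  if (dim(data)[4] != length(b_values)) {
    stop("4th dimension (", dim(data)[4], ") must match the number of b-values (",
         length(b_values), ")")
  }
  ord <- order(b_values)
  scheme <- acquisition_scheme(b_values)
  data <- data[, , , ord, drop = FALSE]
  structure(list(data = data, b = scheme,
                 voxel_size = as.numeric(voxel_size)),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  cat("DWI volume ", paste(dim(x$data)[1:3], collapse = "x"),
      " voxels x ", length(x$b), " b-values; voxel ",
      paste(x$voxel_size, collapse = "x"), " mm\n", sep = "")
  invisible(x)
}

#' Write / read a DWI volume as NIfTI + bval + JSON sidecar
#'
#' The volume is stored as NIfTI-1 (`<prefix>.nii.gz`), its b-values in FSL
#' bval dialect (`<prefix>.bval`) and the voxel size plus units in a JSON
#' sidecar (`<prefix>.json`).
#'
#' @param volume A [dwi_volume()].
#' @param prefix Output path prefix (no extension).
#' @return `write_dwi_volume()` returns the prefix invisibly;
#'   `read_dwi_volume()` returns a [dwi_volume()].
#' @export
write_dwi_volume <- function(volume, prefix) {
  stopifnot(inherits(volume, "dwi_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- c(volume$voxel_size, 1)
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  write_bval(volume$b, paste0(prefix, ".bval"))
  jsonlite::write_json(list(voxel_size_mm = volume$voxel_size,
                            b_units = "s/mm^2"),
                       paste0(prefix, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_dwi_volume
#' @export
read_dwi_volume <- function(prefix) {
  nii <- paste0(prefix, ".nii.gz")
  if (!file.exists(nii)) nii <- paste0(prefix, ".nii")
  if (!file.exists(nii)) stop("NIfTI volume not found: ", prefix, ".nii[.gz]")
  # b-values must stay in file (acquisition) order here: dwi_volume() pairs
  # them with the 4th dimension before canonically sorting both together
  bvals <- scan(paste0(prefix, ".bval"), what = numeric(), quiet = TRUE)
  img <- RNifti::readNifti(nii)
  vs <- RNifti::pixdim(img)[1:3]
  dwi_volume(array(as.numeric(img), dim(img)), bvals, voxel_size = vs)
}

#' Write / read a 3D mask as NIfTI
#'
#' @param mask A logical 3D array or [roi_mask()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @param voxel_size Voxel edge lengths in mm.
#' @return `write_mask_nifti()` returns `path` invisibly; `read_mask_nifti()`
#'   returns a logical 3D array.
#' @export
write_mask_nifti <- function(mask, path, voxel_size = c(1.5, 1.5, 5)) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  img <- RNifti::asNifti(array(as.integer(m), dim(m)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 2) d <- c(d, 1L)  # NIfTI drops trailing singleton dims
  array(as.numeric(img) > 0.5, d)
}

#' Write voxelwise parameter maps as NIfTI files with a JSON sidecar
#'
#' One NIfTI per parameter: D and D* on the x10^-3 mm^2/s reporting scale,
#' f as a fraction; units are recorded in `<prefix>_maps.json`.
#'
#' @param maps An `ivim_maps` object from [fit_ivim_map()].
#' @param prefix Output path prefix.
#' @param voxel_size Voxel edge lengths in mm.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_param_maps <- function(maps, prefix, voxel_size = c(1.5, 1.5, 5)) {
  stopifnot(inherits(maps, "ivim_maps"))
  scale <- c(D = 1e3, f = 1, D_star = 1e3)
  units <- c(D = "x10^-3 mm^2/s", f = "fraction", D_star = "x10^-3 mm^2/s")
  paths <- character(0)
  for (nm in names(scale)) {
    p <- paste0(prefix, "_", nm, ".nii.gz")
    img <- RNifti::asNifti(maps[[nm]] * scale[[nm]])
    RNifti::pixdim(img) <- voxel_size
    RNifti::writeNifti(img, p)
    paths[nm] <- p
  }
  jsonlite::write_json(list(units = as.list(units),
                            missing_value = "NaN outside mask"),
                       paste0(prefix, "_maps.json"), auto_unbox = TRUE)
  invisible(paths)
}
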