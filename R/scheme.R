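#' Diffusion-weighting acquisition scheme
#'
#' An acquisition scheme is the ordered list of b-values (s/mm^2) shared by
#' every signal decay and volume in an analysis. It must start at b = 0,
#' be strictly increasing, and contain no duplicates.
#'
#' @param b_values Numeric vector of b-values in s/mm^2. Sorted ascending
#'   internally; must contain 0 and no duplicates.
#' @return An object of class `acquisition_scheme` (a numeric vector of
#'   b-values with validation applied).
#' @examples
#' acquisition_scheme()            # the default 8-b scheme
#' acquisition_scheme(c(0, 50, 400, 800))
#' @export
acquisition_scheme <- function(b_values = default_b_values()) {
  if (!is.numeric(b_values) || length(b_values) < 2) {
    stop("b_values must be a numeric vector of length >= 2")
  }
  if (anyNA(b_values)) stop("b_values must not contain NA")
  b <- sort(as.numeric(b_values))
  if (any(b < 0)) stop("all b-values must be >= 0")
  if (b[1] != 0) stop("the scheme must contain b = 0")
  if (anyDuplicated(b)) stop("b-values must be distinct")
  structure(b, class = "acquisition_scheme")
}

#' Default eight-b-value thyroid DWI scheme
#'
#' The scheme used throughout: b = 0, 20, 50, 100, 200, 400, 600, 990 s/mm^2,
#' dense at low b to condition the perfusion (fast) compartment and extending
#' to 990 for the diffusion (slow) compartment.
#'
#' @return Numeric vector of eight b-values.
#' @export
default_b_values <- function() {
  c(0, 20, 50, 100, 200, 400, 600, 990)
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat("Acquisition scheme:", length(x), "b-values (s/mm^2):",
      paste(as.numeric(x), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write b-values in FSL bval dialect
#'
#' A bval file is a plain-text file of whitespace-separated b-values on one
#' (or more) lines, in acquisition order.
#'
#' @param path File path.
#' @return `read_bval()` returns an [acquisition_scheme()]; `write_bval()`
#'   returns `path` invisibly.
#' @export
read_bval <- function(path) {
  if (!file.exists(path)) stop("bval file not found: ", path)
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) == 0) stop("bval file is empty: ", path)
  acquisition_scheme(vals)
}

#' @param b_values Numeric vector or `acquisition_scheme`.
#' @rdname read_bval
#' @export
write_bval <- function(b_values, path) {
  cat(paste(as.numeric(b_values), collapse = " "), "\n", sep = "", file = path)
  invisible(path)
}

#' Signal decay along an acquisition scheme
#'
#' Couples a scheme with one positive signal intensity per b-value
#' (arbitrary units). The b = 0 entry plays the role of S0.
#'
#' @param scheme An [acquisition_scheme()].
#' @param S Numeric vector of signal intensities, same length as the scheme,
#'   all strictly positive.
#' @return An object of class `signal_decay` with elements `b` and `S`.
#' @export
signal_decay <- function(scheme, S) {
  scheme <- acquisition_scheme(scheme)
  if (length(S) != length(scheme)) {
    stop("S must have one value per b-value (", length(scheme), ")")
  }
  if (anyNA(S) || any(S <= 0)) stop("all signal intensities must be positive")
  structure(list(b = as.numeric(scheme), S = as.numeric(S)),
            class = "signal_decay")
}
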