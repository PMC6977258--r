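#' Evaluate an expression under a local, explicit RNG state
#'
#' Every stochastic routine in the package takes an explicit seed and runs
#' under this helper, which seeds the RNG for the duration of `expr` and then
#' restores (or removes) the caller's `.Random.seed`, so no hidden global
#' state leaks between calls.
#'
#' @param seed Integer seed (< 2^31).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a deterministic sub-seed for stage `k` of a run seeded with `seed`.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

# Coerce a mask argument (roi_mask, logical or 0/1 numeric array) to a
# logical 3D array and check it matches the expected grid.
as_mask_array <- function(mask, dims) {
  if (inherits(mask, "roi_mask")) mask <- mask$mask
  if (is.null(dim(mask)) || length(dim(mask)) != 3) {
    stop("mask must be a 3D array")
  }
  if (!all(dim(mask) == dims)) {
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match volume grid ", paste(dims, collapse = "x"))
  }
  array(as.logical(mask), dim(mask))
}
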