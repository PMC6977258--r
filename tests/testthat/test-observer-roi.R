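make_test_nodule <- function(seed = 2, ...) {
  generate_nodule(small_spec(...), benign_wl_params(), seed = seed)
}

test_that("zero boundary jitter reproduces the true whole-lesion mask", {
  nod <- make_test_nodule()
  masks <- simulate_observer_masks(nod, observer_model(boundary_jitter = 0),
                                   n_observers = 2, n_sessions = 2, seed = 1)
  wl <- Filter(function(m) m$method == "W-L", masks)
  expect_length(wl, 4)
  for (m in wl) expect_identical(m$mask, nod$true_mask)
})

test_that("single-section ROIs obey the protocol constraints", {
  nod <- make_test_nodule()
  masks <- simulate_observer_masks(nod, observer_model(), 2, 2, seed = 3)
  ss <- Filter(function(m) m$method == "S-S", masks)
  expect_length(ss, 8)  # 2 ROIs x 2 observers x 2 sessions
  for (m in ss) {
    expect_gte(m$n_voxels, 20)
    expect_lte(m$n_voxels, 60)
    expect_length(m$slices, 1)
    expect_true(all(nod$solid_mask[m$mask]))  # solid part only, no cysts
  }
  # the two ROIs of one delineation sit on two distinct slices
  d11 <- Filter(function(m) m$observer == 1 & m$session == 1, ss)
  expect_false(d11[[1]]$slices == d11[[2]]$slices)
})

test_that("mask simulation is deterministic given the seed", {
  nod <- make_test_nodule()
  a <- simulate_observer_masks(nod, observer_model(), 2, 2, seed = 7)
  b <- simulate_observer_masks(nod, observer_model(), 2, 2, seed = 7)
  expect_identical(lapply(a, `[[`, "mask"), lapply(b, `[[`, "mask"))
})

test_that("S-S sampling varies more across observers than W-L on heterogeneous nodules", {
  # full-size nodule: single-section ROIs then subsample the lesion texture
  nod <- generate_nodule(nodule_phantom_spec(cystic_fraction = 0.2),
                         benign_wl_params(), seed = 5)
  wl_means <- c(); ss_means <- c()
  for (s in 1:12) {
    masks <- simulate_observer_masks(nod, observer_model(), 1, 1, seed = s)
    wl <- Filter(function(m) m$method == "W-L", masks)[[1]]
    ss <- Filter(function(m) m$method == "S-S", masks)
    wl_means[s] <- mean(nod$true_params$D[wl$mask])
    ss_means[s] <- mean(c(nod$true_params$D[ss[[1]]$mask],
                          nod$true_params$D[ss[[2]]$mask]))
  }
  expect_gt(var(ss_means), var(wl_means))
})

test_that("roi_mask validates method-specific invariants", {
  m <- array(FALSE, c(8, 8, 3)); m[3:6, 3:6, 2] <- TRUE  # 16 px, 1 slice
  expect_error(roi_mask(m, "S-S"), "20-60")
  m[3:7, 3:7, 2] <- TRUE  # 25 px
  expect_silent(roi_mask(m, "S-S"))
  m[3, 3, 1] <- TRUE
  expect_error(roi_mask(m, "S-S"), "one slice")
  expect_silent(roi_mask(m, "W-L"))
  expect_error(roi_mask(array(FALSE, c(4, 4, 2)), "W-L"), "empty")
})

test_that("summarize_roi is the arithmetic mean over non-missing masked voxels", {
  maps <- list(D = array(2.5, c(3, 3, 1)))
  mask <- array(TRUE, c(3, 3, 1))
  expect_equal(summarize_roi(maps, mask)$D, 2.5)

  maps2 <- list(D = array(NA_real_, c(3, 3, 1)))
  maps2$D[1, 1, 1] <- 1; maps2$D[2, 1, 1] <- 3
  expect_equal(summarize_roi(maps2, mask)$D, 2)       # (1 + 3) / 2
  expect_equal(summarize_roi(maps2, mask)$n_voxels, 2)

  all_na <- list(D = array(NA_real_, c(3, 3, 1)))
  expect_error(summarize_roi(all_na, mask), "no fitted")
})

test_that("ROI means are permutation-invariant and bounded by the voxel range", {
  withr::local_seed(13)
  v <- runif(20)
  maps <- list(D = array(c(v, rep(NA, 7)), c(3, 3, 3)))
  mask <- array(FALSE, c(3, 3, 3)); mask[seq_len(20)] <- TRUE
  s <- summarize_roi(maps, mask)$D
  expect_gte(s, min(v)); expect_lte(s, max(v))
  maps2 <- list(D = array(c(rev(v), rep(NA, 7)), c(3, 3, 3)))
  expect_equal(summarize_roi(maps2, mask)$D, s)
})

test_that("aggregate_ss combines the two ROI means as documented", {
  m1 <- list(D = 1.0, n_voxels = 20)
  m2 <- list(D = 1.2, n_voxels = 60)
  expect_equal(aggregate_ss(m1, m2)$D, 1.1)
  expect_equal(aggregate_ss(m1, m1)$D, 1.0)
  # pixel weighting matches the weighted-mean oracle
  expect_equal(aggregate_ss(m1, m2, weighting = "pixel")$D,
               (20 * 1.0 + 60 * 1.2) / 80)
  expect_error(aggregate_ss(m1), "exactly two")
})

test_that("fit-then-average and average-then-fit agree on homogeneous ROIs", {
  truth <- ivim_params(1.0e-3, 0.35, 11e-3)
  vol <- toy_volume(truth, dims = c(3, 3, 1))
  mask <- array(TRUE, c(3, 3, 1))
  a <- roi_fit_mode(vol, mask, mode = "fit_then_average")
  b <- roi_fit_mode(vol, mask, mode = "average_then_fit")
  expect_equal(a$D, b$D, tolerance = 1e-8)
  expect_equal(a$f, b$f, tolerance = 1e-6)
  expect_error(roi_fit_mode(vol, array(FALSE, c(3, 3, 1))), "empty")
})

test_that("the two fit modes differ by the Jensen gap on heterogeneous ROIs", {
  p1 <- ivim_params(0.6e-3, 0.2, 10e-3)
  p2 <- ivim_params(2.6e-3, 0.5, 20e-3)
  b <- default_b_values()
  sig <- array(0, c(2, 1, 1, 8))
  sig[1, 1, 1, ] <- 1000 * ivim_signal(p1, b)
  sig[2, 1, 1, ] <- 1000 * ivim_signal(p2, b)
  vol <- dwi_volume(sig, b)
  mask <- array(TRUE, c(2, 1, 1))
  a <- roi_fit_mode(vol, mask, mode = "fit_then_average")
  bb <- roi_fit_mode(vol, mask, mode = "average_then_fit")
  expect_equal(a$D, (p1$D + p2$D) / 2, tolerance = 1e-6)  # voxelwise oracle
  expect_gt(abs(a$D - bb$D) / a$D, 0.01)                  # Jensen gap
})
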