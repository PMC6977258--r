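test_that("noiseless bi-exponential decays are recovered to high precision", {
  withr::local_seed(21)
  for (i in 1:100) {
    D <- runif(1, 3e-4, 8e-3)
    truth <- ivim_params(D, runif(1, 0.05, 0.6),
                         runif(1, max(D * 1.5, 4e-3), 4e-2))
    fit <- fit_ivim(toy_decay(truth))
    expect_lt(abs(fit$params$D - truth$D) / truth$D, 1e-3)
    expect_lt(abs(fit$params$f - truth$f) / truth$f, 1e-3)
    expect_lt(abs(fit$params$D_star - truth$D_star) / truth$D_star, 1e-2)
  }
})

test_that("a pure mono-exponential decay fits with vanishing perfusion fraction", {
  b <- default_b_values()
  d <- signal_decay(acquisition_scheme(b), exp(-b * 0.7e-3))
  fit <- fit_ivim(d)
  expect_lte(fit$params$f, 0.005)
  expect_lt(abs(fit$params$D - 0.7e-3) / 0.7e-3, 1e-3)
})

test_that("fitted parameters always satisfy the bound constraints under noise", {
  withr::local_seed(31)
  bb <- ivim_bounds()
  for (i in 1:40) {
    D <- runif(1, 3e-4, 8e-3)
    truth <- ivim_params(D, runif(1, 0.05, 0.6), runif(1, 6e-3, 3e-2))
    S <- 1000 * ivim_signal(truth, default_b_values())
    S <- sqrt((S + rnorm(8, 0, 40))^2 + rnorm(8, 0, 40)^2)
    fit <- fit_ivim(signal_decay(acquisition_scheme(), S))
    p <- fit$params
    expect_true(p$D > 0 && p$D < bb$D_max)
    expect_true(p$D_star > p$D && p$D_star <= bb$D_star_max)
    expect_true(p$f >= 0 && p$f <= 1)
  }
})

test_that("Monte-Carlo noisy fits: D is accurate and D* is the least stable", {
  truth <- malignant_wl_params()
  b <- default_b_values()
  S0 <- 1000; sigma <- 25  # SNR 40 at b = 0
  clean <- S0 * ivim_signal(truth, b)
  fits <- local({
    withr::local_seed(41)
    t(replicate(1000, {
      S <- sqrt((clean + rnorm(8, 0, sigma))^2 + rnorm(8, 0, sigma)^2)
      f <- fit_ivim(signal_decay(acquisition_scheme(), S))
      c(D = f$params$D, f = f$params$f, Ds = f$params$D_star)
    }))
  })
  expect_lt(abs(median(fits[, "D"]) - truth$D) / truth$D, 0.05)
  cv <- function(v) sd(v) / mean(v)
  expect_gt(cv(fits[, "Ds"]), cv(fits[, "D"]))
})

test_that("fit_ivim rejects unusable input", {
  expect_error(signal_decay(acquisition_scheme(), c(-1, rep(1, 7))),
               "positive")
  d3 <- signal_decay(acquisition_scheme(c(0, 100, 600)), c(1, 0.9, 0.6))
  expect_error(fit_ivim(d3), "4 distinct")
})

test_that("two-point ADC inverts the mono-exponential equation", {
  b <- default_b_values()
  d <- signal_decay(acquisition_scheme(b),
                    1000 * exp(-b * 1.5e-3))
  r <- fit_adc_two_point(d, 600)
  expect_equal(r$adc, 1.5e-3, tolerance = 1e-12)
  expect_equal(r$b_pair, c(0, 600))

  flat <- signal_decay(acquisition_scheme(b), rep(1000, 8))
  expect_equal(fit_adc_two_point(flat, 990)$adc, 0)
  expect_error(fit_adc_two_point(d, 800), "not in the acquisition scheme")
})

test_that("two-point ADC of a perfused decay exceeds D (perfusion contamination)", {
  # benign whole-lesion decay: ADC600 = -ln(0.29542)/600 = 2.032e-3
  d <- toy_decay(benign_wl_params())
  adc <- fit_adc_two_point(d, 600)$adc
  expect_equal(adc, 2.032e-3, tolerance = 1e-3)
  expect_gt(adc, benign_wl_params()$D)

  withr::local_seed(51)
  for (i in 1:20) {
    D <- runif(1, 3e-4, 8e-3)
    p <- ivim_params(D, runif(1, 0.02, 0.6), runif(1, 6e-3, 4e-2))
    expect_gt(fit_adc_two_point(toy_decay(p), 990)$adc, p$D)
  }
})

test_that("voxelwise maps recover a homogeneous phantom and flag bad input", {
  truth <- ivim_params(1.1e-3, 0.25, 13e-3)
  vol <- toy_volume(truth, dims = c(3, 3, 2))
  mask <- array(TRUE, c(3, 3, 2))
  maps <- fit_ivim_map(vol, mask)
  expect_equal(max(abs(maps$D[mask] - truth$D)), 0, tolerance = 1e-9)
  expect_equal(max(abs(maps$f[mask] - truth$f)), 0, tolerance = 1e-7)
  expect_true(all(maps$converged[mask]))

  empty <- array(FALSE, c(3, 3, 2))
  expect_error(fit_ivim_map(vol, empty), "empty")
  wrong <- array(TRUE, c(4, 4, 2))
  expect_error(fit_ivim_map(vol, wrong), "grid")
})

test_that("unmasked voxels carry the missing-value sentinel", {
  truth <- ivim_params(1.1e-3, 0.25, 13e-3)
  vol <- toy_volume(truth, dims = c(3, 3, 1))
  mask <- array(FALSE, c(3, 3, 1)); mask[1, 1, 1] <- TRUE
  maps <- fit_ivim_map(vol, mask)
  expect_true(is.na(maps$D[2, 2, 1]))
  expect_false(is.na(maps$D[1, 1, 1]))
})

test_that("per-voxel fits separate a two-compartment phantom", {
  solid <- ivim_params(0.7e-3, 0.3, 11e-3)
  cyst <- ivim_params(2.8e-3, 0.05, 12e-3)
  b <- default_b_values()
  dims <- c(4, 2, 1)
  sig <- array(0, c(dims, 8))
  for (x in 1:4) for (y in 1:2) {
    p <- if (x <= 2) solid else cyst
    sig[x, y, 1, ] <- 1000 * ivim_signal(p, b)
  }
  vol <- dwi_volume(sig, b)
  maps <- fit_ivim_map(vol, array(TRUE, dims))
  expect_equal(maps$D[1, 1, 1], solid$D, tolerance = 1e-6)
  expect_equal(maps$D[4, 2, 1], cyst$D, tolerance = 1e-6)
  expect_equal(maps$f[4, 1, 1], cyst$f, tolerance = 1e-4)
})

test_that("ADC maps equal the closed-form two-point estimate", {
  truth <- ivim_params(1.2e-3, 0.3, 12e-3)
  vol <- toy_volume(truth, dims = c(2, 2, 1))
  mask <- array(TRUE, c(2, 2, 1))
  adc <- fit_adc_map(vol, mask, 600)
  expect_equal(adc[1, 1, 1],
               -log(ivim_signal(truth, 600)) / 600, tolerance = 1e-12)
})
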