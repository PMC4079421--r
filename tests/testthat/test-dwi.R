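single_voxel_field <- function(m, unit = "mm^2/s") {
  D <- array(mat_to_tensor6(m, tol = 1e-6), c(1, 1, 1, 6))
  tensor_field(D, unit = unit)
}

test_that("gradient tables validate their inputs", {
  gt <- default_gradient_table()
  expect_equal(length(gt$bvals), 33)
  expect_equal(gt$n_b0, 1)
  expect_equal(sqrt(rowSums(gt$bvecs[gt$bvals > 0, ]^2)), rep(1, 32),
               tolerance = 1e-12)
  expect_error(gradient_table(c(0, 1000), matrix(0, 3, 3)), "number of volumes")
  expect_error(gradient_table(1000, matrix(0, 1, 3)), "zero gradient")
  expect_warning(gradient_table(1000, matrix(c(1.01, 0, 0), 1, 3)),
                 "renormalizing")
})

test_that("simulated signals follow the Stejskal-Tanner closed forms", {
  gt <- default_gradient_table(n = 6, b = 1000)
  # zero tensor: no attenuation anywhere
  f0 <- single_voxel_field(matrix(0, 3, 3))
  expect_equal(as.vector(simulate_dwi(f0, gt, s0 = 2)$signals), rep(2, 6))
  # isotropic tensor: identical attenuation for all directions
  fi <- single_voxel_field(diag(rep(7e-4, 3)))
  sig <- as.vector(simulate_dwi(fi, gt)$signals)
  expect_equal(sig, rep(exp(-1000 * 7e-4), 6), tolerance = 1e-12)
  # anisotropic tensor with a gradient along its leading eigenvector
  lam <- c(1.5e-3, 3e-4, 3e-4)
  gt1 <- gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  fa1 <- single_voxel_field(diag(lam))
  expect_equal(as.vector(simulate_dwi(fa1, gt1)$signals),
               exp(-1000 * lam[1]), tolerance = 1e-12)
  # cm^2/s fields are converted (1 cm^2 = 100 mm^2)
  fcm <- single_voxel_field(diag(lam) / 100, unit = "cm^2/s")
  expect_equal(simulate_dwi(fcm, gt1)$signals, simulate_dwi(fa1, gt1)$signals)
})

test_that("Rician corruption has the documented statistics", {
  gt <- gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(0, 0, 1)))
  f <- single_voxel_field(diag(rep(5e-4, 3)))
  dwi <- simulate_dwi(f, gt)
  expect_identical(add_rician_noise(dwi, 0)$signals, dwi$signals)

  # zero signal: Rayleigh with mean sigma * sqrt(pi / 2)
  set.seed(41)
  n <- 1e6
  s <- sqrt(stats::rnorm(n)^2 + stats::rnorm(n)^2)
  expect_equal(mean(s), sqrt(pi / 2), tolerance = 2e-3)

  # the same law through the API: corrupt a large constant volume
  D <- array(0, c(200, 200, 1, 6))
  fbig <- tensor_field(D, unit = "mm^2/s")     # zero tensors: signals = s0
  big <- simulate_dwi(fbig, gt, s0 = 1)
  noisy <- add_rician_noise(big, 0.05, seed = 42)
  expect_true(all(noisy$signals >= 0))
  # high SNR: mean slightly above the clean value (Rician bias), sd ~ sigma
  expect_gt(mean(noisy$signals), 1)
  expect_lt(mean(noisy$signals), 1 + 0.05)
  expect_equal(stats::sd(noisy$signals), 0.05, tolerance = 0.02)
})

test_that("noiseless simulate -> fit round trip recovers the tensors", {
  set.seed(43)
  f <- rand_spd_field(nx = 5, ny = 4)
  gt <- default_gradient_table()
  fit <- fit_tensor_lls(simulate_dwi(f, gt), unit = "mm^2/s")
  expect_equal(fit$D, f$D, tolerance = 1e-8)
  expect_true(all(fit$spd[fit$mask]))

  # constant signals at s0 fit the zero tensor
  gt6 <- default_gradient_table(n = 8)
  f0 <- tensor_field(array(0, c(2, 2, 1, 6)), unit = "mm^2/s")
  fit0 <- fit_tensor_lls(simulate_dwi(f0, gt6), unit = "mm^2/s")
  expect_equal(max(abs(fit0$D)), 0, tolerance = 1e-12)
})

test_that("collinear directions are rejected as rank deficient", {
  dirs <- matrix(rep(c(1, 0, 0), 8), ncol = 3, byrow = TRUE)
  gt <- gradient_table(c(0, rep(1000, 8)), rbind(c(0, 0, 0), dirs))
  f <- rand_spd_field(nx = 2, ny = 2)
  dwi <- simulate_dwi(f, gt)
  expect_error(fit_tensor_lls(dwi), "rank-deficient")
})

test_that("unbiased NLM reproduces its closed form on constant images", {
  gt <- gradient_table(c(0, 1000), rbind(c(0, 0, 0), c(0, 0, 1)))
  f <- tensor_field(array(0, c(12, 12, 1, 6)), unit = "mm^2/s")
  dwi <- simulate_dwi(f, gt, s0 = 3)     # all signals exactly 3

  out0 <- unlm_dwi(dwi, sigma = 0)
  expect_equal(out0$signals, dwi$signals)

  s <- 0.4
  out <- unlm_dwi(dwi, sigma = s)
  # NLM of a constant field is the constant; bias correction is exact
  expect_equal(as.vector(out$signals), rep(sqrt(9 - 2 * s^2), 144),
               tolerance = 1e-10)
  expect_error(unlm_dwi(dwi, sigma = -1), "nonnegative")
  expect_error(unlm_dwi(simulate_dwi(f, gt)), "unknown")
})

test_that("unbiased NLM in DWI space reduces tensor-fit error on noisy data", {
  spec <- small_phantom_spec()
  truth <- generate_phantom(spec)
  gt <- default_gradient_table()
  noisy_dwi <- add_rician_noise(simulate_dwi(truth, gt), 0.05, seed = 44)
  noisy <- fit_tensor_lls(noisy_dwi)
  den <- fit_tensor_lls(unlm_dwi(noisy_dwi))
  ev_noisy <- evaluate_field(noisy, truth)
  ev_den <- evaluate_field(den, truth)
  expect_lt(ev_den$mean_pd_deviation, ev_noisy$mean_pd_deviation)
})
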