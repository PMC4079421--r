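test_that("angular deviation is sign-invariant, symmetric, and bounded", {
  a <- c(1, 0, 0)
  expect_equal(angular_deviation(a, a), 0)
  expect_equal(angular_deviation(a, -a), 0)
  expect_equal(angular_deviation(a, c(1, 1, 0) / sqrt(2)), 45)
  expect_equal(angular_deviation(a, c(0, 1, 0)), 90)
  expect_error(angular_deviation(a, c(0, 0, 0)), "zero vector")
  set.seed(61)
  for (rep in 1:50) {
    u <- stats::rnorm(3); v <- stats::rnorm(3)
    d <- angular_deviation(u, v)
    expect_equal(d, angular_deviation(v, u))
    expect_equal(d, angular_deviation(-u, v))
    expect_true(d >= 0 && d <= 90)
  }
})

test_that("a field evaluated against itself scores zero", {
  ph <- generate_phantom(small_phantom_spec())
  # against its own eigenvectors the deviation is exactly zero
  ev_own <- evaluate_field(ph, ph, truth_pd = field_pd(ph))
  expect_identical(ev_own$mean_pd_deviation, 0)
  # against the analytic tangent map only eigensolver rounding remains
  # (acos has infinite slope at 1, so machine eps shows up as ~1e-8 deg)
  ev <- evaluate_field(ph, ph)
  expect_lt(ev$mean_pd_deviation, 1e-5)
  expect_equal(ev$mean_fa_deviation, 0)
  expect_equal(ev$n_pd, sum(ph$fiber))
})

test_that("an in-plane 90-degree rotation scores 90 degrees of PD deviation", {
  ph <- generate_phantom(phantom_spec(shape = c(24, 24), amplitude = 0,
                                      period = 24, half_width = 2))
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  rot <- ph
  for (v in which(ph$fiber)) {
    ij <- arrayInd(v, dim(ph$fiber))
    m <- R %*% field_tensor(ph, ij[1], ij[2]) %*% t(R)
    rot$D[ij[1], ij[2], 1, ] <- mat_to_tensor6(m, tol = 1e-6)
  }
  ev <- evaluate_field(rot, ph)
  expect_equal(ev$mean_pd_deviation, 90, tolerance = 1e-8)
})

test_that("identical fields give zero-width permutation confidence intervals", {
  ph <- generate_phantom(small_phantom_spec())
  u <- permutation_uncertainty(ph, ph, default_gradient_table(), n_perm = 20,
                               seed = 1)
  expect_equal(u$ci_width, rep(0, 6), tolerance = 1e-15)
  expect_equal(u$mean_tensor,
               tensor6_to_mat(field_values(ph)[u$voxel, ]),
               tolerance = 1e-8)
  expect_true(all(u$lower <= u$mean + 1e-15) &&
              all(u$mean <= u$upper + 1e-15))
})

test_that("confidence widths grow monotonically with residual magnitude", {
  spec <- small_phantom_spec()
  truth <- generate_phantom(spec)
  gt <- default_gradient_table()
  noisy <- fit_tensor_lls(add_rician_noise(simulate_dwi(truth, gt), 0.05,
                                           seed = 62))
  widths <- sapply(c(0.5, 1, 2), function(scale) {
    blend <- truth
    blend$D <- truth$D + scale * (noisy$D - truth$D)
    sum(permutation_uncertainty(truth, blend, gt, n_perm = 300,
                                seed = 63)$ci_width)
  })
  expect_true(all(diff(widths) > 0))
})

test_that("permutation replicates are reproducible and near-normal coverage holds", {
  spec <- small_phantom_spec()
  truth <- generate_phantom(spec)
  gt <- default_gradient_table()
  noisy <- fit_tensor_lls(add_rician_noise(simulate_dwi(truth, gt), 0.01,
                                           seed = 64))
  a <- permutation_uncertainty(truth, noisy, gt, n_perm = 1000, seed = 65)
  b <- permutation_uncertainty(truth, noisy, gt, n_perm = 1000, seed = 65)
  expect_identical(a$replicates, b$replicates)
  # 95% normal-fit intervals should cover ~95% of replicates per component
  cover <- sapply(1:6, function(c6)
    mean(a$replicates[, c6] >= a$lower[c6] & a$replicates[, c6] <= a$upper[c6]))
  expect_true(all(abs(cover - 0.95) < 0.02))
})

test_that("the per-direction permutation scope is supported", {
  ph <- generate_phantom(small_phantom_spec())
  gt <- default_gradient_table()
  noisy <- fit_tensor_lls(add_rician_noise(simulate_dwi(ph, gt), 0.05,
                                           seed = 66))
  u <- permutation_uncertainty(ph, noisy, gt, n_perm = 100, seed = 67,
                               scope = "per_direction")
  expect_true(all(u$ci_width > 0))
})
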