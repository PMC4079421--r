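constant_field <- function(nx = 5L, ny = 5L, t6 = c(3, 0.2, 2, 0.1, 0, 1)) {
  D <- array(rep(t6, each = nx * ny), c(nx, ny, 1L, 6L))
  tensor_field(D, unit = "mm^2/s")
}

test_that("weights are uniform on a constant field and normalized everywhere", {
  f <- constant_field()
  for (metric in c("euclidean", "riemannian", "log_euclidean")) {
    w <- nlm_weights(c(3, 3), f, nlm_config(metric = metric))
    expect_equal(nrow(w$coords), 25)
    expect_equal(w$weights, rep(1 / 25, 25))
  }
  # window clipped at a corner: 3x3 of the 5x5 survives, still normalized
  w <- nlm_weights(c(1, 1), f, nlm_config())
  expect_equal(nrow(w$coords), 9)
  expect_equal(sum(w$weights), 1, tolerance = 1e-12)
})

test_that("a very large decay constant makes the weights uniform", {
  set.seed(31)
  f <- perturbed_field()
  w <- nlm_weights(c(3, 3), f,
                   nlm_config(h = 1e9, h_mode = "absolute"))
  expect_equal(w$weights, rep(1 / 25, 25), tolerance = 1e-10)
})

test_that("weights on a 1D toy field match hand-evaluated exponential weighting", {
  t6s <- list(c(1, 0, 1, 0, 0, 1), c(2, 0, 2, 0, 0, 2), c(5, 0, 4, 0, 0, 3))
  D <- array(0, c(3, 1, 1, 6))
  for (i in 1:3) D[i, 1, 1, ] <- t6s[[i]]
  f <- tensor_field(D, unit = "mm^2/s")
  h <- 2.5
  w <- nlm_weights(c(2, 1), f,
                   nlm_config(metric = "euclidean", search_window = 3,
                              h = h, h_mode = "absolute"))
  # hand evaluation: full-matrix Frobenius distances from voxel 2
  d2 <- sapply(t6s, function(v) {
    a <- tensor6_to_mat(f$D[2, 1, 1, ]); b <- tensor6_to_mat(v)
    sum((a - b)^2)
  })
  expected <- exp(-d2 / h^2)
  expected <- expected / sum(expected)
  expect_equal(w$weights, expected, tolerance = 1e-12)
  # weights do not increase with distance
  expect_true(all(diff(w$weights[order(d2)]) <= 1e-15))
})

test_that("a constant field is a fixed point of the filter", {
  f <- constant_field()
  for (metric in c("euclidean", "riemannian", "log_euclidean")) {
    out <- denoise_nlm(f, nlm_config(metric = metric))
    expect_equal(out$D, f$D, tolerance = 1e-10)
  }
})

test_that("uniform weights over two tensors give the matrix geometric mean", {
  A <- diag(c(4, 1, 1))
  B <- diag(c(1, 4, 2))
  D <- array(0, c(2, 1, 1, 6))
  D[1, 1, 1, ] <- mat_to_tensor6(A)
  D[2, 1, 1, ] <- mat_to_tensor6(B)
  f <- tensor_field(D, unit = "mm^2/s")
  out <- denoise_nlm(f, nlm_config(search_window = 3, h = 1e9,
                                   h_mode = "absolute"))
  gm <- exp_spd((log_spd(A) + log_spd(B)) / 2)
  expect_equal(tensor6_to_mat(out$D[1, 1, 1, ]), gm, tolerance = 1e-8)
  expect_equal(tensor6_to_mat(out$D[2, 1, 1, ]), gm, tolerance = 1e-8)
})

test_that("every output tensor is SPD even when the input is not", {
  set.seed(32)
  f <- perturbed_field(nx = 8, ny = 8)
  # corrupt a few voxels into non-SPD territory
  f$D[2, 3, 1, 1] <- -0.5
  f$D[5, 6, 1, 3] <- -1
  for (metric in c("euclidean", "riemannian", "log_euclidean")) {
    out <- denoise_nlm(f, nlm_config(metric = metric))
    spd <- field_spd_mask(out)
    expect_true(all(spd[out$mask]))
  }
})

test_that("filtering commutes with a mirror flip of the field", {
  # reflect along x: voxel (i,j) -> (nx+1-i, j), tensor D -> S D S with
  # S = diag(-1, 1, 1); all three metrics are invariant under this
  # congruence, so denoising must commute with the flip.
  set.seed(33)
  f <- perturbed_field(nx = 7, ny = 5)
  S <- diag(c(-1, 1, 1))
  flip <- function(fld) {
    D <- fld$D[rev(seq_len(dim(fld$D)[1])), , , , drop = FALSE]
    for (i in seq_len(dim(D)[1])) for (j in seq_len(dim(D)[2]))
      D[i, j, 1, ] <- mat_to_tensor6(S %*% tensor6_to_mat(D[i, j, 1, ]) %*% S)
    tensor_field(D, unit = fld$unit)
  }
  for (metric in c("euclidean", "log_euclidean")) {
    a <- denoise_nlm(flip(f), nlm_config(metric = metric))
    b <- flip(denoise_nlm(f, nlm_config(metric = metric)))
    expect_equal(a$D, b$D, tolerance = 1e-9)
  }
})

test_that("masked-out voxels pass through and do not contaminate neighbors", {
  set.seed(34)
  f <- perturbed_field(nx = 5, ny = 5)
  mask <- array(TRUE, c(5, 5, 1))
  mask[3, 3, 1] <- FALSE
  g <- tensor_field(f$D, mask = mask, unit = f$unit)
  out <- denoise_nlm(g, nlm_config())
  expect_equal(out$D[3, 3, 1, ], g$D[3, 3, 1, ])   # untouched
  w <- nlm_weights(c(2, 3), g, nlm_config())
  expect_false(any(w$coords[, 1] == 3 & w$coords[, 2] == 3))
})

test_that("Gaussian filtering preserves constants and reproduces its kernel", {
  f <- constant_field(7, 7)
  out <- gaussian_filter_tensor(f, window = 5, sigma = 1)
  expect_equal(out$D, f$D, tolerance = 1e-12)

  # impulse response: center voxel 1 in one component, rest zero
  D <- array(0, c(9, 9, 1, 6))
  D[5, 5, 1, 1] <- 1
  imp <- tensor_field(D, unit = "mm^2/s")
  out <- gaussian_filter_tensor(imp, window = 5, sigma = 1.3)
  offs <- as.matrix(expand.grid(-2:2, -2:2))
  k <- exp(-rowSums(offs^2) / (2 * 1.3^2))
  k <- k / sum(k)    # interior voxels see the full window
  for (r in seq_len(nrow(offs)))
    expect_equal(out$D[5 + offs[r, 1], 5 + offs[r, 2], 1, 1], k[r],
                 tolerance = 1e-12)
  expect_equal(out$D[5, 5, 1, 2], 0)
})

test_that("patchwise distances still yield normalized, sensible weights", {
  set.seed(35)
  f <- perturbed_field(nx = 7, ny = 7)
  w <- nlm_weights(c(4, 4), f, nlm_config(patch_radius = 1))
  expect_equal(sum(w$weights), 1, tolerance = 1e-12)
  expect_true(all(w$weights > 0))
  out <- denoise_nlm(f, nlm_config(patch_radius = 1))
  expect_true(all(field_spd_mask(out)[out$mask]))
})

test_that("configuration validation rejects bad parameters", {
  expect_error(nlm_config(search_window = 4), "odd")
  expect_error(nlm_config(search_window = 1), "odd")
  expect_error(nlm_config(h = 0), "positive")
  expect_error(nlm_config(patch_radius = -1), ">= 0")
  expect_error(nlm_weights(c(1, 1), constant_field(),
                           nlm_config(search_window = 99)), NA)
})
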