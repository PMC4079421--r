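# Shared generators for random SPD tensors, rotations, and small fields.
# Callers are responsible for set.seed(); everything here is RNG-driven.

rand_spd <- function(scale = 1, jitter = 0.1) {
  A <- matrix(stats::rnorm(9), 3L, 3L)
  (A %*% t(A) + jitter * diag(3L)) * scale
}

rand_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L, 3L))
  Q <- qr.Q(qr_)
  Q %*% diag(sign(diag(qr.R(qr_))))  # det may be -1; fine for congruence
}

# Small random SPD tensor field at diffusivity scale (trace ~ 2e-3 mm^2/s
# when scale = 1e-3) for fit round-trips.
rand_spd_field <- function(nx = 4L, ny = 3L, scale = 1e-3) {
  D <- array(0, c(nx, ny, 1L, 6L))
  for (i in seq_len(nx)) for (j in seq_len(ny))
    D[i, j, 1L, ] <- mat_to_tensor6(rand_spd(scale = scale / 3), tol = 1e-6)
  tensor_field(D, unit = "mm^2/s")
}

# Reduced phantom for fast pipeline tests.
small_phantom_spec <- function(...) {
  phantom_spec(shape = c(32L, 32L), amplitude = 6, period = 24,
               half_width = 2, ...)
}

# Field whose voxels are mild perturbations of a base tensor (always SPD).
perturbed_field <- function(nx = 6L, ny = 6L, base = diag(c(3, 2, 1)),
                            sd = 0.05) {
  D <- array(0, c(nx, ny, 1L, 6L))
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    E <- matrix(stats::rnorm(9, sd = sd), 3L, 3L)
    D[i, j, 1L, ] <- mat_to_tensor6(base + E %*% t(E), tol = 1e-6)
  }
  tensor_field(D, unit = "mm^2/s")
}
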