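# Synthetic sinusoid-fiber DTI phantom. A single-slice field containing a
# curved fiber bundle whose principal direction follows the tangent of
# y = A sin(2 pi x / T), embedded in an isotropic background of the same
# trace. Fiber tensors are axially symmetric with exactly the requested
# trace and FA, so construction exactness is testable to machine precision.

#' Phantom specification
#'
#' @param shape Grid shape in voxels, `c(nx, ny)` (single slice).
#' @param amplitude Sinusoid amplitude in voxels.
#' @param period Sinusoid period in voxels.
#' @param half_width Fiber-bundle half-width in voxels (vertical distance
#'   from the center line).
#' @param trace Fiber tensor trace (default 2.1e-5 cm^2/sec, a typical
#'   brain-parenchyma value).
#' @param fa Fiber fractional anisotropy in (0, 1) (default 0.8, typical of
#'   coherent white matter).
#' @param bg_trace Background tensor trace; defaults to the fiber trace.
#' @param bg_fa Background FA; the default 0 gives isotropic background
#'   tensors.
#' @param unit Diffusivity unit of `trace`.
#' @param seed Recorded for provenance; generation itself is deterministic
#'   and does not consume random numbers.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L), amplitude = 12, period = 48,
                         half_width = 3, trace = 2.1e-5, fa = 0.8,
                         bg_trace = trace, bg_fa = 0,
                         unit = c("cm^2/s", "mm^2/s"), seed = 0L) {
  unit <- match.arg(unit)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 4L),
            period > 0, half_width >= 0, trace > 0, bg_trace > 0,
            fa >= 0, fa < 1, bg_fa >= 0, bg_fa < 1)
  if (shape[2L] / 2 + amplitude + half_width >= shape[2L] ||
      shape[2L] / 2 - amplitude - half_width <= 0)
    stop("fiber bundle does not fit inside the grid")
  structure(list(shape = shape, amplitude = amplitude, period = period,
                 half_width = half_width, trace = trace, fa = fa,
                 bg_trace = bg_trace, bg_fa = bg_fa, unit = unit,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Axially symmetric eigenvalues with prescribed trace and FA
#'
#' Solves the two constraints trace and FA for the unique eigenvalue triple
#' with `lambda2 == lambda3`. Writing `lambda1 = T/3 + 2 d` and
#' `lambda2 = lambda3 = T/3 - d`, FA reduces to
#' `3 d / sqrt(T^2/3 + 6 d^2)`, giving the closed form
#' `d = FA * T / sqrt(27 - 18 FA^2)`. For FA in \[0, 1) all three
#' eigenvalues are strictly positive.
#'
#' @param trace Tensor trace (> 0).
#' @param fa Fractional anisotropy in \[0, 1).
#' @return Numeric vector `(lambda1, lambda2, lambda3)` with
#'   `lambda1 >= lambda2 == lambda3 > 0`.
#' @export
axially_symmetric_eigenvalues <- function(trace, fa) {
  if (trace <= 0) stop("trace must be positive")
  if (fa < 0 || fa >= 1)
    stop("fa must lie in [0, 1) for an axially symmetric tensor")
  d <- fa * trace / sqrt(27 - 18 * fa^2)
  c(trace / 3 + 2 * d, trace / 3 - d, trace / 3 - d)
}

#' Generate the sinusoid-fiber phantom
#'
#' Voxels within `half_width` (vertically) of the center line
#' `y = ny/2 + A sin(2 pi x / T)` carry axially symmetric tensors whose
#' leading eigenvector is the unit tangent of the curve; all other voxels
#' carry background tensors (isotropic by default). The fiber/background
#' boundary is sharp — there are no partial-volume voxels — so
#' edge-preservation of filters is directly measurable.
#'
#' @param spec A [phantom_spec()].
#' @return A [tensor_field()] with two extra elements: `fiber`, the logical
#'   fiber mask, and `pd`, the ground-truth principal-direction map
#'   (`(nx, ny, 1, 3)`, zero outside the fiber).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  nx <- spec$shape[1L]; ny <- spec$shape[2L]
  lam_f <- axially_symmetric_eigenvalues(spec$trace, spec$fa)
  lam_b <- axially_symmetric_eigenvalues(spec$bg_trace, spec$bg_fa)

  D <- array(0, c(nx, ny, 1L, 6L))
  fiber <- array(FALSE, c(nx, ny, 1L))
  pd <- array(0, c(nx, ny, 1L, 3L))

  # background: axially symmetric about x (isotropic when bg_fa = 0)
  bg6 <- mat_to_tensor6(diag(lam_b))
  for (c6 in 1:6) D[, , 1L, c6] <- bg6[c6]

  omega <- 2 * pi / spec$period
  for (i in seq_len(nx)) {
    x <- i - 1
    y0 <- ny / 2 + spec$amplitude * sin(omega * x)
    slope <- spec$amplitude * omega * cos(omega * x)
    tangent <- c(1, slope, 0) / sqrt(1 + slope^2)
    e2 <- c(-tangent[2L], tangent[1L], 0)
    e3 <- c(0, 0, 1)
    Q <- cbind(tangent, e2, e3)
    t6 <- mat_to_tensor6(Q %*% (lam_f * t(Q)), tol = 1e-6)
    in_fiber <- which(abs(seq_len(ny) - 1 - y0) <= spec$half_width)
    for (j in in_fiber) {
      D[i, j, 1L, ] <- t6
      fiber[i, j, 1L] <- TRUE
      pd[i, j, 1L, ] <- fix_direction_sign(tangent)
    }
  }
  field <- tensor_field(D, voxdim = c(1, 1, 1), unit = spec$unit)
  field$fiber <- fiber
  field$pd <- pd
  field$spec <- spec
  field
}
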