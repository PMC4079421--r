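# Bridge between tensor space and diffusion-weighted image (DWI) space:
# Stejskal-Tanner signal simulation, Rician corruption, linear least-squares
# tensor estimation, and the unbiased NLM baseline that denoises each DWI
# volume separately.

#' Diffusion gradient table
#'
#' @param bvals Numeric vector of b-values in sec/mm^2; zero entries are
#'   baseline (b0) volumes and may carry zero direction vectors.
#' @param bvecs Direction matrix, one row per volume (n x 3). Rows for b > 0
#'   must be unit vectors; off-unit rows (within reason) are renormalized
#'   with a warning.
#' @return An object of class `gradient_table` with elements `bvals`,
#'   `bvecs`, and `n_b0`.
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- unname(as.numeric(bvals))
  bvecs <- unname(as.matrix(bvecs))
  if (ncol(bvecs) != 3L) stop("bvecs must have 3 columns (x, y, z)")
  if (nrow(bvecs) != length(bvals))
    stop("bvals and bvecs disagree on the number of volumes")
  if (any(bvals < 0)) stop("negative b-value")
  nrm <- sqrt(rowSums(bvecs^2))
  dw <- bvals > 0
  if (any(nrm[dw] == 0)) stop("zero gradient vector with b > 0")
  if (any(abs(nrm[dw] - 1) > 1e-3))
    warning("gradient directions off unit norm by > 1e-3; renormalizing")
  bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm[dw]
  structure(list(bvals = bvals, bvecs = bvecs, n_b0 = sum(!dw)),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("gradient table: %d diffusion directions (b = %s), %d b0\n",
              sum(x$bvals > 0),
              paste(unique(x$bvals[x$bvals > 0]), collapse = ", "), x$n_b0))
  invisible(x)
}

# Deterministic Fibonacci-spiral points on the upper hemisphere: closed
# form, no RNG, well spread under antipodal identification (minimum axis
# separation ~13 degrees at n = 32).
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 1
  z <- (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Default 32-direction gradient scheme
#'
#' A deterministic set of `n` well-spread, pairwise non-collinear unit
#' directions (Fibonacci hemisphere) at a single b-value, preceded by
#' `n_b0` baseline volumes. Matches the fixture files shipped under
#' `inst/extdata`.
#'
#' @param n Number of diffusion directions.
#' @param b b-value in sec/mm^2.
#' @param n_b0 Number of b = 0 baseline volumes.
#' @return A [gradient_table()].
#' @export
default_gradient_table <- function(n = 32L, b = 1000, n_b0 = 1L) {
  dirs <- fibonacci_hemisphere(n)
  gradient_table(c(rep(0, n_b0), rep(b, n)),
                 rbind(matrix(0, n_b0, 3L), dirs))
}

# Design row g -> (gx^2, 2 gx gy, gy^2, 2 gx gz, 2 gy gz, gz^2), the
# quadratic form g^T D g in lower-triangular component order.
design_rows <- function(bvecs) {
  cbind(bvecs[, 1L]^2, 2 * bvecs[, 1L] * bvecs[, 2L], bvecs[, 2L]^2,
        2 * bvecs[, 1L] * bvecs[, 3L], 2 * bvecs[, 2L] * bvecs[, 3L],
        bvecs[, 3L]^2)
}

#' Simulate diffusion-weighted signals from a tensor field
#'
#' Stejskal-Tanner attenuation `a_i = s0 * exp(-b g_i^T D g_i)` per voxel
#' and direction. Field components are converted internally to mm^2/s so
#' that b in sec/mm^2 gives a dimensionless exponent.
#'
#' @param field A [tensor_field()].
#' @param gtab A [gradient_table()].
#' @param s0 Baseline signal (arbitrary units); the default 1 makes a noise
#'   standard deviation of 0.05 exactly "5 percent" noise.
#' @return An object of class `dwi_set`: list with `s0` (3D baseline
#'   volume), `signals` (4D array, one volume per diffusion direction),
#'   `gtab`, `mask`, `voxdim`, and `sigma` (NA until noise is added).
#' @export
simulate_dwi <- function(field, gtab, s0 = 1) {
  if (s0 <= 0) stop("s0 must be positive")
  dw <- gtab$bvals > 0
  if (!any(dw)) stop("gradient table has no diffusion-weighted volumes")
  nrm <- sqrt(rowSums(gtab$bvecs[dw, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("non-unit gradient direction")
  sp <- field_spatial_dim(field)
  V <- field_values(field) * unit_to_mm2(field$unit)
  G <- design_rows(gtab$bvecs[dw, , drop = FALSE]) * gtab$bvals[dw]
  att <- exp(-V %*% t(G))            # nvox x ndir
  structure(list(s0 = array(s0, sp),
                 signals = array(s0 * att, c(sp, sum(dw))),
                 gtab = gtab, mask = field$mask, voxdim = field$voxdim,
                 sigma = NA_real_),
            class = "dwi_set")
}

#' @export
print.dwi_set <- function(x, ...) {
  sp <- dim(x$s0)
  cat(sprintf("DWI set: %d x %d x %d voxels, %d directions, sigma %s\n",
              sp[1], sp[2], sp[3], dim(x$signals)[4L],
              ifelse(is.na(x$sigma), "unknown", format(x$sigma))))
  invisible(x)
}

#' Corrupt DWI signals with Rician noise
#'
#' Each magnitude signal `a` is replaced by `sqrt((a + x)^2 + y^2)` with
#' `x, y ~ N(0, sigma^2)` independent, the standard model of magnitude MRI
#' noise. The baseline volume is corrupted too. `sigma = 0` returns the
#' input exactly.
#'
#' @param dwi A `dwi_set`.
#' @param sigma Gaussian component standard deviation (same units as the
#'   signals).
#' @param seed Optional integer fixing the noise stream.
#' @return A `dwi_set` with nonnegative signals and `sigma` recorded.
#' @export
add_rician_noise <- function(dwi, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be nonnegative")
  out <- dwi
  out$sigma <- sigma
  if (sigma == 0) return(out)
  if (!is.null(seed)) set.seed(seed)
  rician <- function(a) {
    n <- length(a)
    sqrt((a + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  }
  out$s0 <- array(rician(dwi$s0), dim(dwi$s0))
  out$signals <- array(rician(dwi$signals), dim(dwi$signals))
  out
}

#' Linear least-squares tensor estimation
#'
#' Per voxel, solves `ln s = ln S0 - b g^T D g` by ordinary least squares
#' over all volumes (baseline included), estimating the six tensor
#' components and `ln S0` jointly. Signals are clamped to `eps` before the
#' log. Fitted tensors are symmetric but not necessarily positive definite;
#' the SPD status of each masked voxel is reported alongside.
#'
#' @param dwi A `dwi_set` with at least 6 non-collinear diffusion
#'   directions plus a baseline (design matrix rank 7).
#' @param unit Diffusivity unit for the returned field.
#' @param eps Positive clamp applied to signals before the log transform.
#' @return A [tensor_field()]; element `spd` is a logical array flagging
#'   which masked voxels came out positive definite.
#' @export
fit_tensor_lls <- function(dwi, unit = c("cm^2/s", "mm^2/s"), eps = 1e-12) {
  unit <- match.arg(unit)
  gtab <- dwi$gtab
  dw <- gtab$bvals > 0
  X <- cbind(-design_rows(gtab$bvecs[dw, , drop = FALSE]) * gtab$bvals[dw], 1)
  X <- rbind(c(rep(0, 6L), 1), X)    # baseline row
  if (qr(X)$rank < 7L)
    stop("rank-deficient design matrix: directions are collinear")
  sp <- dim(dwi$s0)
  nvox <- prod(sp)
  S <- cbind(as.vector(dwi$s0),
             matrix(dwi$signals, nvox, dim(dwi$signals)[4L]))
  Y <- log(pmax(t(S), eps))          # nvol x nvox
  beta <- solve(crossprod(X), crossprod(X, Y))   # 7 x nvox
  D <- t(beta[1:6, , drop = FALSE]) / unit_to_mm2(unit)
  field <- tensor_field(array(D, c(sp, 6L)), mask = dwi$mask,
                        voxdim = dwi$voxdim, unit = unit)
  field$spd <- field_spd_mask(field)
  field
}

# ---- unbiased NLM in DWI space -------------------------------------------

#' Configuration for unbiased NLM in DWI space
#'
#' Defaults follow common practice for magnitude-MRI NLM: an 11x11 search
#' window, patch radius 1, and decay `h = h_factor * sigma * sqrt(patch
#' size)`.
#'
#' @param search_window Odd in-plane search window edge (voxels).
#' @param patch_radius Patch radius in voxels (patch edge `2r + 1`).
#' @param h_factor Multiplier in `h = h_factor * sigma * sqrt(n_patch)`.
#' @return An object of class `unlm_config`.
#' @export
unlm_config <- function(search_window = 11L, patch_radius = 1L,
                        h_factor = 1.2) {
  search_window <- as.integer(search_window)
  if (search_window < 3L || search_window %% 2L == 0L)
    stop("search_window must be an odd integer >= 3")
  if (patch_radius < 0L) stop("patch_radius must be >= 0")
  if (h_factor <= 0) stop("h_factor must be positive")
  structure(list(search_window = search_window,
                 patch_radius = as.integer(patch_radius),
                 h_factor = h_factor),
            class = "unlm_config")
}

# For a 2D slice of shape sp2 and offset (dx, dy): linear index of
# (i + dx, j + dy) per pixel, NA outside the slice.
slice_shift_index <- function(sp2, dx, dy) {
  i <- rep.int(seq_len(sp2[1L]), sp2[2L]) + dx
  j <- rep(seq_len(sp2[2L]), each = sp2[1L]) + dy
  ok <- i >= 1L & i <= sp2[1L] & j >= 1L & j <= sp2[2L]
  out <- rep(NA_integer_, sp2[1L] * sp2[2L])
  out[ok] <- i[ok] + (j[ok] - 1L) * sp2[1L]
  out
}

# NLM of the squared intensities of all volumes of one slice at once.
# M: npix x nvol matrix. Returns the weighted average of squared shifted
# intensities (the quantity the unbiased estimator corrects).
unlm_slice_sq <- function(M, sp2, cfg, h) {
  r <- (cfg$search_window - 1L) %/% 2L
  pr <- cfg$patch_radius
  npix <- nrow(M)
  search <- expand.grid(dx = -r:r, dy = -r:r)
  patch <- expand.grid(dx = -pr:pr, dy = -pr:pr)
  pmaps <- lapply(seq_len(nrow(patch)),
                  function(u) slice_shift_index(sp2, patch$dx[u], patch$dy[u]))
  n_patch <- nrow(patch)
  num <- matrix(0, npix, ncol(M))
  den <- matrix(0, npix, ncol(M))
  for (o in seq_len(nrow(search))) {
    smap <- slice_shift_index(sp2, search$dx[o], search$dy[o])
    Ms <- M[smap, , drop = FALSE]          # NA rows where out of bounds
    ssd <- (M - Ms)^2
    valid <- as.numeric(!is.na(smap))
    ssd[is.na(ssd)] <- 0
    # patch-aggregated distance, renormalized where the patch is clipped
    pssd <- matrix(0, npix, ncol(M))
    pcnt <- numeric(npix)
    for (u in seq_len(n_patch)) {
      pm <- pmaps[[u]]
      ok <- !is.na(pm)
      pssd[ok, ] <- pssd[ok, ] + ssd[pm[ok], , drop = FALSE]
      pcnt[ok] <- pcnt[ok] + valid[pm[ok]]
    }
    d2 <- pssd * ifelse(pcnt > 0, n_patch / pcnt, 0)
    w <- exp(-d2 / h^2) * valid * as.numeric(pcnt > 0)
    Ms[is.na(Ms)] <- 0
    num <- num + w * Ms^2
    den <- den + w
  }
  num / den    # den >= 1: the self offset always contributes weight 1
}

#' Unbiased non-local means denoising in DWI space
#'
#' Classical patchwise NLM applied to every volume of the set independently
#' (baseline included), with the Rician bias removed by averaging squared
#' magnitudes and subtracting `2 sigma^2`:
#' `v_hat = sqrt(max(NLM(v^2) - 2 sigma^2, 0))`.
#' Volumes are processed slice by slice.
#'
#' @param dwi A `dwi_set`.
#' @param sigma Noise standard deviation; defaults to the value recorded on
#'   the set by [add_rician_noise()].
#' @param cfg An [unlm_config()].
#' @return A denoised `dwi_set`.
#' @export
unlm_dwi <- function(dwi, sigma = dwi$sigma, cfg = unlm_config()) {
  if (is.na(sigma)) stop("sigma is unknown; pass it explicitly")
  if (sigma < 0) stop("sigma must be nonnegative")
  sp <- dim(dwi$s0)
  ndir <- dim(dwi$signals)[4L]
  n_patch <- (2L * cfg$patch_radius + 1L)^2
  h <- cfg$h_factor * sigma * sqrt(n_patch)
  out <- dwi
  for (k in seq_len(sp[3L])) {
    M <- cbind(as.vector(dwi$s0[, , k]),
               matrix(dwi$signals[, , k, ], sp[1L] * sp[2L], ndir))
    msq <- if (h > 0) unlm_slice_sq(M, sp[1:2], cfg, h) else M^2
    v <- sqrt(pmax(msq - 2 * sigma^2, 0))
    out$s0[, , k] <- v[, 1L]
    out$signals[, , k, ] <- v[, -1L]
  }
  out
}
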