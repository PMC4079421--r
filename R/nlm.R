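# Tensor-space non-local means.
#
# For a voxel p the filter averages the log-tensors of the search window,
#   V(p) <- exp( sum_q w(p,q) log V(q) ),
# the geometric mean of the neighborhood, so the output is SPD by
# construction. Weights follow the classical NLM form
#   w(p,q) = exp(-d^2(p,q) / h^2) / Z(p),  Z(p) = sum_q exp(-d^2(p,q)/h^2),
# with d a tensor distance (Euclidean, Riemannian, or Log-Euclidean) rather
# than a gray-level difference. The center voxel itself belongs to the
# window with d(p,p) = 0.

#' NLM filter configuration
#'
#' @param metric Tensor distance used for weighting: `"log_euclidean"`
#'   (default), `"riemannian"`, or `"euclidean"`.
#' @param search_window Odd window edge length in voxels (>= 3); the
#'   reference setting for this family of filters is a 5x5 in-plane window.
#' @param h Decay constant of the exponential weighting in `absolute` mode,
#'   in the units of the chosen tensor distance.
#' @param h_mode `"median_scaled"` (default): the effective decay is
#'   `h_rel` times the median nonzero tensor distance inside each voxel's
#'   search window, making the filter invariant to the overall tensor scale;
#'   `"absolute"`: use `h` literally.
#' @param h_rel Relative decay multiplier for `median_scaled` mode.
#' @param patch_radius 0 (default) compares single tensors; `r >= 1`
#'   averages squared tensor distances over aligned `(2r+1)`-wide patches.
#' @param eigenvalue_floor Relative floor applied to tensor eigenvalues
#'   before matrix logs (see [log_spd()]); guards against non-SPD voxels
#'   from noisy least-squares fits.
#' @param search_3d Use a cubic window on volumes; single-slice fields are
#'   always filtered in-plane.
#' @return An object of class `nlm_config`.
#' @export
nlm_config <- function(metric = c("log_euclidean", "riemannian", "euclidean"),
                       search_window = 5L, h = 30, h_mode = c("median_scaled",
                                                              "absolute"),
                       h_rel = 1, patch_radius = 0L, eigenvalue_floor = 1e-12,
                       search_3d = FALSE) {
  metric <- match.arg(metric)
  h_mode <- match.arg(h_mode)
  search_window <- as.integer(search_window)
  if (search_window < 3L || search_window %% 2L == 0L)
    stop("search_window must be an odd integer >= 3")
  if (h <= 0) stop("h must be positive")
  if (h_rel <= 0) stop("h_rel must be positive")
  if (patch_radius < 0L) stop("patch_radius must be >= 0")
  structure(list(metric = metric, search_window = search_window, h = h,
                 h_mode = h_mode, h_rel = h_rel,
                 patch_radius = as.integer(patch_radius),
                 eigenvalue_floor = eigenvalue_floor,
                 search_3d = isTRUE(search_3d)),
            class = "nlm_config")
}

#' @export
print.nlm_config <- function(x, ...) {
  cat(sprintf(
    "NLM config: metric %s, window %d, h %s (%s), patch radius %d\n",
    x$metric, x$search_window, format(x$h), x$h_mode, x$patch_radius))
  invisible(x)
}

# Integer offset matrix (n x 3) for a centered window of edge length `win`;
# z offsets only when the field is 3D and a cubic window was requested.
window_offsets <- function(win, sp, use_3d) {
  r <- (win - 1L) %/% 2L
  zr <- if (use_3d && sp[3L] > 1L) r else 0L
  as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -zr:zr))
}

# Precompute everything the per-voxel weight kernel needs.
nlm_context <- function(field, cfg) {
  sp <- field_spatial_dim(field)
  V <- field_values(field)
  L <- field_log_values(field, cfg$eigenvalue_floor)
  Wh <- NULL
  if (cfg$metric == "riemannian") {
    # whitening matrix A^{-1/2} per voxel (symmetric, stored as 6-vectors)
    Wh <- matrix(NA_real_, nrow(V), 6L)
    for (v in which(field$mask)) {
      m <- floor_eigenvalues(tensor6_to_mat(V[v, ]), cfg$eigenvalue_floor)
      e <- eigen(m, symmetric = TRUE)
      w <- e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
      Wh[v, ] <- mat_to_tensor6(w, tol = 1e-6)
    }
  }
  list(sp = sp, mask = field$mask, V = V, L = L, Wh = Wh,
       offsets = window_offsets(cfg$search_window, sp, cfg$search_3d),
       patch_offsets = if (cfg$patch_radius > 0L)
         window_offsets(2L * cfg$patch_radius + 1L, sp, cfg$search_3d))
}

# Masked neighbor voxels of a center (i, j, k): returns their (n x 3)
# coordinates and linear indices.
neighbor_indices <- function(ctx, center) {
  nb <- ctx$offsets + rep(center, each = nrow(ctx$offsets))
  ok <- nb[, 1L] >= 1L & nb[, 1L] <= ctx$sp[1L] &
        nb[, 2L] >= 1L & nb[, 2L] <= ctx$sp[2L] &
        nb[, 3L] >= 1L & nb[, 3L] <= ctx$sp[3L]
  nb <- nb[ok, , drop = FALSE]
  lin <- nb[, 1L] + (nb[, 2L] - 1L) * ctx$sp[1L] +
    (nb[, 3L] - 1L) * ctx$sp[1L] * ctx$sp[2L]
  keep <- ctx$mask[lin]
  list(coords = nb[keep, , drop = FALSE], lin = lin[keep])
}

# Squared tensor distances from the voxel with linear index p to neighbors
# `nb` (linear indices), under the configured metric. Distances at the
# numerical noise floor are snapped to exact zero so that fields with
# duplicated tensors (and in particular constant fields) see them as
# identical; without the snap, median-scaled weighting would normalize by
# rounding error.
point_dist2 <- function(ctx, cfg, p, nb) {
  frob2_row <- function(v)
    v[1L]^2 + 2 * v[2L]^2 + v[3L]^2 + 2 * v[4L]^2 + 2 * v[5L]^2 + v[6L]^2
  snap <- function(d2, floor2) { d2[d2 <= floor2] <- 0; d2 }
  switch(cfg$metric,
    euclidean = snap(frob2_rows(ctx$V[nb, , drop = FALSE], ctx$V[p, ]),
                     1e-18 * frob2_row(ctx$V[p, ])),
    log_euclidean = snap(frob2_rows(ctx$L[nb, , drop = FALSE], ctx$L[p, ]),
                         max(1e-18 * frob2_row(ctx$L[p, ]), 1e-20)),
    riemannian = {
      wp <- tensor6_to_mat(ctx$Wh[p, ])
      snap(vapply(nb, function(q) {
        if (q == p) return(0)
        m <- wp %*% tensor6_to_mat(ctx$V[q, ]) %*% wp
        ev <- eigen((m + t(m)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values
        sum(log(pmax(ev, .Machine$double.xmin))^2)
      }, numeric(1)), 1e-20)
    })
}

# Patch-averaged squared distance: mean of point distances over aligned
# patch offsets for which both shifted voxels are in-bounds and masked.
patch_dist2 <- function(ctx, cfg, pc, nbc) {
  d2 <- numeric(nrow(nbc))
  cnt <- numeric(nrow(nbc))
  for (r in seq_len(nrow(ctx$patch_offsets))) {
    o <- ctx$patch_offsets[r, ]
    pp <- pc + o
    qq <- nbc + rep(o, each = nrow(nbc))
    okp <- all(pp >= 1L) && all(pp <= ctx$sp)
    if (!okp) next
    plin <- pp[1L] + (pp[2L] - 1L) * ctx$sp[1L] +
      (pp[3L] - 1L) * ctx$sp[1L] * ctx$sp[2L]
    if (!ctx$mask[plin]) next
    okq <- qq[, 1L] >= 1L & qq[, 1L] <= ctx$sp[1L] &
           qq[, 2L] >= 1L & qq[, 2L] <= ctx$sp[2L] &
           qq[, 3L] >= 1L & qq[, 3L] <= ctx$sp[3L]
    qlin <- rep(NA_integer_, nrow(nbc))
    qlin[okq] <- qq[okq, 1L] + (qq[okq, 2L] - 1L) * ctx$sp[1L] +
      (qq[okq, 3L] - 1L) * ctx$sp[1L] * ctx$sp[2L]
    okq[okq] <- ctx$mask[qlin[okq]]
    if (!any(okq)) next
    d2[okq] <- d2[okq] + point_dist2(ctx, cfg, plin, qlin[okq])
    cnt[okq] <- cnt[okq] + 1
  }
  ifelse(cnt > 0, d2 / cnt, 0)
}

nlm_dist2 <- function(ctx, cfg, center, nbs) {
  if (cfg$patch_radius > 0L) patch_dist2(ctx, cfg, center, nbs$coords)
  else {
    p <- center[1L] + (center[2L] - 1L) * ctx$sp[1L] +
      (center[3L] - 1L) * ctx$sp[1L] * ctx$sp[2L]
    point_dist2(ctx, cfg, p, nbs$lin)
  }
}

# Normalized weights from squared distances under the configured h mode.
weights_from_dist2 <- function(d2, cfg) {
  h <- if (cfg$h_mode == "absolute") cfg$h else {
    pos <- d2 > 0
    if (!any(pos)) return(rep(1 / length(d2), length(d2)))
    cfg$h_rel * stats::median(sqrt(d2[pos]))
  }
  w <- exp(-d2 / h^2)
  w / sum(w)
}

#' NLM weights at one voxel
#'
#' Exposes the weighting kernel of [denoise_nlm()] for inspection: the
#' normalized weight of every masked voxel in the search window centered on
#' `center`.
#'
#' @param center Voxel coordinate `c(i, j)` or `c(i, j, k)` (1-based); must
#'   lie inside the mask.
#' @param field A [tensor_field()].
#' @param cfg An [nlm_config()].
#' @return List with `coords` (n x 3 matrix of neighbor voxel coordinates)
#'   and `weights` (positive, summing to 1, non-increasing in tensor
#'   distance).
#' @export
nlm_weights <- function(center, field, cfg = nlm_config()) {
  if (length(center) == 2L) center <- c(center, 1L)
  center <- as.integer(center)
  sp <- field_spatial_dim(field)
  if (any(center < 1L) || any(center > sp))
    stop("center voxel is outside the field")
  if (!field$mask[center[1L], center[2L], center[3L]])
    stop("center voxel is outside the mask")
  ctx <- nlm_context(field, cfg)
  nbs <- neighbor_indices(ctx, center)
  if (nrow(nbs$coords) == 0L) stop("empty neighborhood")
  d2 <- nlm_dist2(ctx, cfg, center, nbs)
  list(coords = nbs$coords, weights = weights_from_dist2(d2, cfg))
}

#' Denoise a tensor field by non-local means in tensor space
#'
#' Replaces every masked tensor with the weighted geometric mean of its
#' search window: weights decay exponentially with the chosen tensor
#' distance, and averaging happens in the matrix-log domain, so every output
#' tensor is symmetric positive definite. Voxels outside the mask are copied
#' through unchanged.
#'
#' @param field A [tensor_field()] whose masked voxels are valid tensors
#'   (eigenvalues are floored per `cfg$eigenvalue_floor` before logs).
#' @param cfg An [nlm_config()].
#' @return A [tensor_field()] with the same shape, mask, and unit.
#' @export
denoise_nlm <- function(field, cfg = nlm_config()) {
  ctx <- nlm_context(field, cfg)
  V_out <- ctx$V
  idx <- which(field$mask)
  coords <- arrayInd(idx, ctx$sp)
  for (r in seq_along(idx)) {
    center <- coords[r, ]
    nbs <- neighbor_indices(ctx, center)
    d2 <- nlm_dist2(ctx, cfg, center, nbs)
    w <- weights_from_dist2(d2, cfg)
    lbar <- colSums(w * ctx$L[nbs$lin, , drop = FALSE])
    V_out[idx[r], ] <- mat_to_tensor6(exp_spd(tensor6_to_mat(lbar)))
  }
  values_to_field(V_out, field)
}

#' Gaussian filtering of a tensor field (baseline)
#'
#' Component-wise Gaussian-weighted averaging of the six tensor components
#' over a centered window, with weights renormalized where the window is
#' clipped by the mask or the image edge. The classical linear baseline: it
#' smooths homogeneous regions but blurs fiber boundaries, and its output is
#' not guaranteed SPD (though averages of SPD tensors are).
#'
#' @param field A [tensor_field()].
#' @param window Odd window edge length in voxels.
#' @param sigma Gaussian kernel standard deviation in voxels.
#' @param use_3d Use a cubic window on volumes.
#' @return A filtered [tensor_field()].
#' @export
gaussian_filter_tensor <- function(field, window = 5L, sigma = 1,
                                   use_3d = FALSE) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd")
  if (sigma <= 0) stop("sigma must be positive")
  sp <- field_spatial_dim(field)
  V <- field_values(field)
  offs <- window_offsets(window, sp, use_3d)
  kern <- exp(-rowSums(offs^2) / (2 * sigma^2))

  nvox <- prod(sp)
  ii <- rep.int(seq_len(sp[1L]), sp[2L] * sp[3L])
  jj <- rep.int(rep(seq_len(sp[2L]), each = sp[1L]), sp[3L])
  kk <- rep(seq_len(sp[3L]), each = sp[1L] * sp[2L])
  num <- matrix(0, nvox, 6L)
  den <- numeric(nvox)
  for (r in seq_len(nrow(offs))) {
    i2 <- ii + offs[r, 1L]; j2 <- jj + offs[r, 2L]; k2 <- kk + offs[r, 3L]
    ok <- i2 >= 1L & i2 <= sp[1L] & j2 >= 1L & j2 <= sp[2L] &
      k2 >= 1L & k2 <= sp[3L]
    src <- i2[ok] + (j2[ok] - 1L) * sp[1L] + (k2[ok] - 1L) * sp[1L] * sp[2L]
    keep <- field$mask[src]
    dst <- which(ok)[keep]
    src <- src[keep]
    num[dst, ] <- num[dst, ] + kern[r] * V[src, , drop = FALSE]
    den[dst] <- den[dst] + kern[r]
  }
  out <- V
  msk <- which(field$mask)
  out[msk, ] <- num[msk, , drop = FALSE] / den[msk]
  values_to_field(out, field)
}
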