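# TensorField: a spatial grid of diffusion tensors with a foreground mask.
# Internally always a 4D array (nx, ny, nz, 6); single-slice (2D) data use
# nz = 1. Component order is the package-wide lower-triangular convention.

#' Construct a tensor field
#'
#' @param D Numeric array of tensor components: `(nx, ny, 6)` for a single
#'   slice or `(nx, ny, nz, 6)` for a volume, last dimension in
#'   `(Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)` order.
#' @param mask Logical array of spatial shape `(nx, ny[, nz])` marking
#'   foreground voxels; `NULL` means all voxels are foreground.
#' @param voxdim Voxel size in mm per spatial axis (length 3).
#' @param unit Diffusivity unit of the stored components, `"cm^2/s"`
#'   (the default, matching the phantom) or `"mm^2/s"`.
#' @return An object of class `tensor_field`: a list with elements `D`
#'   (4D array), `mask` (3D logical), `voxdim`, and `unit`.
#' @export
tensor_field <- function(D, mask = NULL, voxdim = c(1, 1, 1),
                         unit = c("cm^2/s", "mm^2/s")) {
  unit <- match.arg(unit)
  d <- dim(D)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)) || d[length(d)] != 6L)
    stop("D must be an (nx, ny[, nz], 6) array of tensor components")
  if (length(d) == 3L) dim(D) <- c(d[1L], d[2L], 1L, 6L)
  sp <- dim(D)[1:3]
  if (is.null(mask)) {
    mask <- array(TRUE, sp)
  } else {
    if (is.null(dim(mask))) stop("mask must be an array")
    md <- dim(mask)
    if (length(md) == 2L) dim(mask) <- c(md, 1L)
    if (!all(dim(mask) == sp))
      stop("mask shape does not match the tensor grid")
    mask <- array(as.logical(mask), sp)
  }
  if (!all(is.finite(D[rep(mask, 6L)])))
    stop("non-finite tensor components inside the mask")
  if (length(voxdim) == 2L) voxdim <- c(voxdim, 1)
  stopifnot(length(voxdim) == 3L, all(voxdim > 0))
  structure(list(D = D, mask = mask, voxdim = as.numeric(voxdim),
                 unit = unit),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  sp <- dim(x$D)[1:3]
  cat(sprintf("tensor field: %d x %d x %d voxels (%d masked), unit %s\n",
              sp[1], sp[2], sp[3], sum(x$mask), x$unit))
  invisible(x)
}

field_spatial_dim <- function(field) dim(field$D)[1:3]

# Tensor components as an (nvox, 6) matrix, voxels in array (column-major)
# linear order.
field_values <- function(field) {
  D <- field$D
  d <- dim(D)
  dim(D) <- c(prod(d[1:3]), 6L)
  D
}

values_to_field <- function(V, template) {
  D <- template$D
  D[] <- V
  out <- template
  out$D <- D
  out
}

#' Extract one tensor from a field
#'
#' @param field A [tensor_field()].
#' @param i,j,k 1-based voxel indices (`k = 1` for single-slice fields).
#' @return A 3x3 symmetric matrix.
#' @export
field_tensor <- function(field, i, j, k = 1L) {
  tensor6_to_mat(field$D[i, j, k, ])
}

# Eigendecompose every masked voxel. Returns values (nvox x 3, descending)
# and vectors (nvox x 3 x 3, [, , l] the l-th eigenvector); NA outside mask.
field_eigen <- function(field, vectors = TRUE) {
  V <- field_values(field)
  nvox <- nrow(V)
  idx <- which(field$mask)
  vals <- matrix(NA_real_, nvox, 3L)
  vecs <- if (vectors) array(NA_real_, c(nvox, 3L, 3L)) else NULL
  for (v in idx) {
    m <- tensor6_to_mat(V[v, ])
    if (vectors) {
      e <- eigen(m, symmetric = TRUE)
      vals[v, ] <- e$values
      vecs[v, , ] <- e$vectors
    } else {
      vals[v, ] <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    }
  }
  list(values = vals, vectors = vecs)
}

#' Fractional anisotropy map of a tensor field
#'
#' @param field A [tensor_field()].
#' @return Numeric array of the field's spatial shape; `NA` outside the mask.
#' @export
field_fa <- function(field) {
  e <- field_eigen(field, vectors = FALSE)
  fa <- rep(NA_real_, nrow(e$values))
  idx <- which(field$mask)
  for (v in idx) fa[v] <- fa_from_eigenvalues(e$values[v, ])
  array(fa, field_spatial_dim(field))
}

#' Principal-direction map of a tensor field
#'
#' @param field A [tensor_field()].
#' @return Array `(nx, ny, nz, 3)` of unit vectors (sign-normalized as in
#'   [principal_direction()]); `NA` outside the mask.
#' @export
field_pd <- function(field) {
  e <- field_eigen(field)
  sp <- field_spatial_dim(field)
  pd <- array(NA_real_, c(prod(sp), 3L))
  for (v in which(field$mask)) {
    vec <- e$vectors[v, , 1L]
    pd[v, ] <- fix_direction_sign(vec / sqrt(sum(vec^2)))
  }
  array(pd, c(sp, 3L))
}

#' Validate that all masked tensors are SPD
#'
#' @param field A [tensor_field()].
#' @param floor Strict lower bound for eigenvalues.
#' @return Logical array of the spatial shape: `TRUE` where the masked voxel
#'   holds an SPD tensor, `NA` outside the mask.
#' @export
field_spd_mask <- function(field, floor = 0) {
  e <- field_eigen(field, vectors = FALSE)
  ok <- rep(NA, nrow(e$values))
  for (v in which(field$mask)) ok[v] <- all(e$values[v, ] > floor)
  array(ok, field_spatial_dim(field))
}

# Per-voxel matrix log of all masked tensors, with eigenvalue flooring.
# Returns an (nvox, 6) matrix of log-tensor components (NA outside mask).
field_log_values <- function(field, floor = 1e-12) {
  V <- field_values(field)
  L <- matrix(NA_real_, nrow(V), 6L)
  for (v in which(field$mask)) {
    m <- floor_eigenvalues(tensor6_to_mat(V[v, ]), floor)
    e <- eigen(m, symmetric = TRUE)
    if (any(e$values <= 0))
      stop(sprintf("voxel %d is not SPD even after eigenvalue flooring", v))
    lm <- e$vectors %*% (log(e$values) * t(e$vectors))
    L[v, ] <- mat_to_tensor6(lm, tol = 1e-6)
  }
  L
}

# Convert field components between diffusivity units; returns the factor
# that maps the field's unit to mm^2/s (1 cm^2 = 100 mm^2).
unit_to_mm2 <- function(unit) switch(unit, "cm^2/s" = 100, "mm^2/s" = 1,
                                     stop("unknown diffusivity unit: ", unit))
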