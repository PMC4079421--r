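# Algebra on 3x3 symmetric positive-definite (SPD) diffusion tensors.
#
# Storage convention for 6-component vectors is lower-triangular, row by row:
# (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz). This matches the common 6-component NIfTI
# tensor layout and is enforced throughout the package.

#' Convert a 6-component tensor vector to a 3x3 symmetric matrix
#'
#' The component order is lower-triangular: `(Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)`.
#'
#' @param v Numeric vector of length 6.
#' @return A 3x3 symmetric numeric matrix.
#' @seealso [mat_to_tensor6()]
#' @export
#' @examples
#' tensor6_to_mat(c(1, 0, 2, 0, 0, 3))  # diag(1, 2, 3)
tensor6_to_mat <- function(v) {
  if (length(v) != 6L || !is.numeric(v))
    stop("tensor vector must be numeric of length 6")
  matrix(c(v[1L], v[2L], v[4L],
           v[2L], v[3L], v[5L],
           v[4L], v[5L], v[6L]), 3L, 3L)
}

#' Convert a 3x3 symmetric matrix to the 6-component tensor vector
#'
#' @param m A 3x3 numeric matrix, symmetric to within `tol` (relative to its
#'   largest absolute entry).
#' @param tol Relative symmetry tolerance.
#' @return Numeric vector `(Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)`.
#' @export
mat_to_tensor6 <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || !all(dim(m) == c(3L, 3L)))
    stop("expected a 3x3 matrix")
  scale <- max(abs(m), 1e-300)
  if (max(abs(m - t(m))) > tol * scale)
    stop("matrix is not symmetric within tolerance")
  c(m[1L, 1L], m[2L, 1L], m[2L, 2L], m[3L, 1L], m[3L, 2L], m[3L, 3L])
}

# Coerce a 6-vector or 3x3 matrix to a symmetric 3x3 matrix, checking
# finiteness. Used by every tensor-level operation.
as_tensor_mat <- function(t) {
  m <- if (is.matrix(t)) {
    if (!all(dim(t) == c(3L, 3L))) stop("tensor matrix must be 3x3")
    (t + t(t)) / 2
  } else {
    tensor6_to_mat(t)
  }
  if (!all(is.finite(m))) stop("tensor has non-finite components")
  m
}

#' Eigendecomposition of a diffusion tensor
#'
#' Eigenvalues are returned sorted descending (lambda1 >= lambda2 >= lambda3)
#' with the corresponding orthonormal eigenvectors as columns.
#'
#' @param t A tensor: 6-component vector or 3x3 symmetric matrix.
#' @return An object of class `tensor_spectrum`: a list with `values`
#'   (length 3, descending) and `vectors` (3x3, columns are eigenvectors).
#' @details A warning (not an error) is issued when an eigenvalue is
#'   non-positive, since linear least-squares fits of noisy data can produce
#'   non-SPD tensors that still have a well-defined spectrum.
#' @export
eig_spd <- function(t) {
  m <- as_tensor_mat(t)
  e <- eigen(m, symmetric = TRUE)   # already sorted descending
  if (any(e$values <= 0))
    warning("tensor is not positive definite (eigenvalue <= 0)")
  structure(list(values = e$values, vectors = e$vectors),
            class = "tensor_spectrum")
}

#' @export
print.tensor_spectrum <- function(x, ...) {
  cat("tensor spectrum\n  eigenvalues:", format(x$values, digits = 6), "\n")
  invisible(x)
}

#' Is a tensor symmetric positive definite?
#'
#' @param t A tensor (6-vector or 3x3 matrix).
#' @param floor Eigenvalues must exceed `floor` (default 0) to count as SPD.
#' @return Logical scalar.
#' @export
is_spd_tensor <- function(t, floor = 0) {
  m <- as_tensor_mat(t)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > floor)
}

# Clamp eigenvalues of a symmetric matrix from below at rel * sum(|lambda|).
# Guards matrix logs against non-SPD tensors from noisy fits.
floor_eigenvalues <- function(m, rel = 1e-12) {
  e <- eigen(m, symmetric = TRUE)
  scale <- sum(abs(e$values))
  if (scale == 0) stop("cannot floor the zero tensor")
  lam <- pmax(e$values, rel * scale)
  e$vectors %*% (lam * t(e$vectors))
}

#' Matrix logarithm of an SPD tensor
#'
#' Computed spectrally as `Q diag(log lambda) Q^T`.
#'
#' @param t A strictly positive-definite tensor (6-vector or 3x3 matrix).
#' @param floor Optional relative eigenvalue floor: eigenvalues below
#'   `floor * sum(|lambda|)` are clamped before taking logs. `NULL` (default)
#'   raises an error on any non-positive eigenvalue instead.
#' @return A symmetric 3x3 matrix (generally not SPD).
#' @export
log_spd <- function(t, floor = NULL) {
  m <- as_tensor_mat(t)
  if (!is.null(floor)) m <- floor_eigenvalues(m, floor)
  e <- eigen(m, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("tensor is not positive definite; cannot take matrix log ",
         "(supply `floor` to clamp eigenvalues)")
  e$vectors %*% (log(e$values) * t(e$vectors))
}

#' Matrix exponential of a symmetric matrix
#'
#' The exponential of any symmetric matrix is SPD, so this is the inverse of
#' [log_spd()] and the final step of geometric-mean tensor averaging.
#'
#' @param s A symmetric 3x3 matrix (checked to relative tolerance `tol`).
#' @param tol Relative symmetry tolerance.
#' @return A 3x3 SPD matrix.
#' @export
exp_spd <- function(s, tol = 1e-8) {
  if (!is.matrix(s) || !all(dim(s) == c(3L, 3L)))
    stop("expected a 3x3 matrix")
  if (!all(is.finite(s))) stop("matrix has non-finite components")
  scale <- max(abs(s), 1)
  if (max(abs(s - t(s))) > tol * scale)
    stop("matrix is not symmetric within tolerance")
  s <- (s + t(s)) / 2
  e <- eigen(s, symmetric = TRUE)
  e$vectors %*% (exp(e$values) * t(e$vectors))
}

# FA from a length-3 eigenvalue vector; clipped to [0, 1].
fa_from_eigenvalues <- function(lam) {
  ss <- sum(lam^2)
  if (ss == 0) return(0)
  fa <- sqrt(1.5 * sum((lam - mean(lam))^2) / ss)
  min(max(fa, 0), 1)
}

#' Fractional anisotropy
#'
#' `FA = sqrt(3/2) * sqrt(sum((lambda_i - mean(lambda))^2)) / sqrt(sum(lambda_i^2))`,
#' clipped to \[0, 1\]. FA is 0 for isotropic diffusion and approaches 1 as
#' diffusion collapses onto a single axis.
#'
#' @param t A tensor (6-vector or 3x3 matrix).
#' @return Dimensionless scalar in \[0, 1\]. The zero tensor returns 0 with a
#'   warning.
#' @export
fractional_anisotropy <- function(t) {
  m <- as_tensor_mat(t)
  lam <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (all(lam == 0)) {
    warning("zero tensor: FA defined as 0")
    return(0)
  }
  fa_from_eigenvalues(lam)
}

# Fix the arbitrary sign of an axial direction: first component larger than
# `tol` in absolute value is made positive.
fix_direction_sign <- function(v, tol = 1e-12) {
  i <- which(abs(v) > tol)
  if (length(i) == 0L) return(v)
  if (v[i[1L]] < 0) -v else v
}

#' Principal diffusion direction
#'
#' The unit eigenvector of the largest eigenvalue, the local proxy for fiber
#' orientation. The eigenvector sign is physically arbitrary (the direction
#' is axial); the convention here makes the first nonzero component positive
#' so outputs are reproducible.
#'
#' @param t A tensor (6-vector or 3x3 matrix).
#' @param tol Relative tolerance for detecting a degenerate leading
#'   eigenvalue (lambda1 == lambda2).
#' @return Unit 3-vector. Degenerate tensors (lambda1 ~ lambda2) warn and
#'   return the first eigenvector deterministically.
#' @export
principal_direction <- function(t, tol = 1e-8) {
  e <- eig_spd(as_tensor_mat(t))
  lam <- e$values
  scale <- max(abs(lam), 1e-300)
  if ((lam[1L] - lam[2L]) <= tol * scale)
    warning("degenerate principal direction (lambda1 ~ lambda2); ",
            "returning the first eigenvector")
  v <- e$vectors[, 1L]
  fix_direction_sign(v / sqrt(sum(v^2)))
}

#' Trace of a diffusion tensor
#'
#' Equals the sum of the three eigenvalues; `trace/3` is the mean
#' diffusivity.
#'
#' @param t A tensor (6-vector or 3x3 matrix).
#' @return Scalar in the tensor's diffusivity unit.
#' @export
trace_of <- function(t) {
  if (!is.matrix(t) && length(t) == 6L) return(sum(t[c(1L, 3L, 6L)]))
  m <- as_tensor_mat(t)
  sum(diag(m))
}
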