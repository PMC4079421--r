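# The three tensor similarity measures used for NLM weighting.
#
# Euclidean: Frobenius norm of the difference, defined on all symmetric
#   matrices, rotation invariant.
# Riemannian: affine-invariant geodesic distance on the SPD manifold,
#   sqrt(sum(log^2 eigenvalues of A^{-1}B)).
# Log-Euclidean: Frobenius norm of the difference of matrix logs; agrees
#   with the Riemannian distance whenever the tensors commute and is much
#   cheaper on fields (one log per voxel instead of one eigensystem per
#   pair).

#' Euclidean (Frobenius) distance between tensors
#'
#' `||A - B||_F` on the full 3x3 matrices, so off-diagonal components count
#' twice. Defined for any symmetric matrices; positive-definiteness is not
#' required.
#'
#' @param a,b Tensors (6-vectors or 3x3 symmetric matrices).
#' @return Nonnegative scalar.
#' @export
euclidean_distance <- function(a, b) {
  d <- as_tensor_mat(a) - as_tensor_mat(b)
  sqrt(sum(d * d))
}

# Eigenvalues of A^{-1} B via the symmetric similar matrix
# A^{-1/2} B A^{-1/2} (same spectrum, numerically stable).
similarity_eigenvalues <- function(a, b) {
  ea <- eigen(a, symmetric = TRUE)
  if (any(ea$values <= 0)) stop("first tensor is not positive definite")
  w <- ea$vectors %*% ((1 / sqrt(ea$values)) * t(ea$vectors))
  m <- w %*% b %*% w
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("second tensor is not positive definite")
  ev
}

#' Affine-invariant Riemannian distance between SPD tensors
#'
#' `sqrt(sum_i log^2 lambda_i)` where `lambda_i` are the (real, positive)
#' eigenvalues of `A^{-1} B`. Invariant under congruence `X -> M X M^T` for
#' any invertible `M`. Computed on the symmetrized form
#' `A^{-1/2} B A^{-1/2}`, which has the same spectrum.
#'
#' @param a,b Strictly SPD tensors (6-vectors or 3x3 symmetric matrices).
#' @return Nonnegative scalar; zero iff `a == b`.
#' @export
riemannian_distance <- function(a, b) {
  ev <- similarity_eigenvalues(as_tensor_mat(a), as_tensor_mat(b))
  sqrt(sum(log(ev)^2))
}

#' Log-Euclidean distance between SPD tensors
#'
#' `||log(A) - log(B)||_F`, the Frobenius norm of the matrix-log difference
#' (equivalently `sqrt(Trace[(log A - log B)^2])`). A true metric on SPD
#' matrices, rotation and scaling invariant, and equal to the Riemannian
#' distance whenever `A` and `B` commute.
#'
#' @param a,b Strictly SPD tensors (6-vectors or 3x3 symmetric matrices).
#' @return Nonnegative scalar; zero iff `a == b`.
#' @export
log_euclidean_distance <- function(a, b) {
  d <- log_spd(a) - log_spd(b)
  sqrt(sum(d * d))
}

#' Tensor distance under a selectable metric
#'
#' @param a,b Tensors.
#' @param metric One of `"euclidean"`, `"riemannian"`, `"log_euclidean"`.
#' @return Nonnegative scalar.
#' @export
tensor_distance <- function(a, b,
                            metric = c("log_euclidean", "riemannian",
                                       "euclidean")) {
  metric <- match.arg(metric)
  switch(metric,
         euclidean = euclidean_distance(a, b),
         riemannian = riemannian_distance(a, b),
         log_euclidean = log_euclidean_distance(a, b))
}

# Squared Frobenius norm of the difference of two 6-component rows, with
# off-diagonal components (positions 2, 4, 5) counted twice. Vectorized over
# rows; the workhorse for Euclidean and Log-Euclidean NLM weighting.
frob2_rows <- function(V, w) {
  d <- V - rep(w, each = nrow(V))
  d <- d * d
  d[, 1L] + 2 * d[, 2L] + d[, 3L] + 2 * d[, 4L] + 2 * d[, 5L] + d[, 6L]
}
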