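## Exact algebra linking a Gaussian precision matrix to node-wise regression
## coefficients, partial correlations, and edge weights.

#' Validate and symmetrize a precision matrix
#'
#' Checks that `omega` is a symmetric positive-definite matrix with a strictly
#' positive diagonal, symmetrizing it as `(omega + t(omega)) / 2` first so that
#' floating-point asymmetry from I/O round trips is tolerated.
#'
#' @param omega Square numeric matrix, the candidate precision matrix
#'   (inverse covariance).
#' @param tol Relative eigenvalue tolerance: the smallest eigenvalue must
#'   exceed `tol` times the largest for the matrix to count as positive
#'   definite.
#' @return The symmetrized matrix, invisibly usable in downstream algebra.
#' @export
check_precision <- function(omega, tol = 1e-10) {
  if (!is.matrix(omega) || !is.numeric(omega) || nrow(omega) != ncol(omega))
    stop("'omega' must be a square numeric matrix")
  if (any(!is.finite(omega)))
    stop("'omega' contains non-finite values")
  omega <- (omega + t(omega)) / 2
  if (any(diag(omega) <= 0))
    stop("precision matrix has a non-positive diagonal entry")
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol * max(ev))
    stop("precision matrix is not positive definite")
  omega
}

#' Partial correlations from a precision matrix
#'
#' Computes the matrix of partial correlations
#' \eqn{\pi_{k'k} = -\omega_{k'k} / \sqrt{\omega_{k'k'} \omega_{kk}}} for
#' \eqn{k' \neq k}, with a zero diagonal. Under a multivariate Gaussian,
#' \eqn{\pi_{k'k}} is the correlation between the residuals of the two optimal
#' linear regressions of genes \eqn{k'} and \eqn{k} on all remaining genes, and
#' is zero exactly when the two genes are conditionally independent.
#'
#' @param omega Symmetric positive-definite precision matrix.
#' @return Symmetric matrix of partial correlations in \eqn{[-1, 1]} with zero
#'   diagonal; dimnames are carried over.
#' @export
#' @examples
#' omega <- rbind(c(2, 1, 0), c(1, 2, 1), c(0, 1, 2))
#' partial_corr_from_precision(omega)
partial_corr_from_precision <- function(omega) {
  omega <- check_precision(omega)
  d <- sqrt(diag(omega))
  pi_mat <- -omega / tcrossprod(d)
  diag(pi_mat) <- 0
  pi_mat
}

#' Node-wise regression coefficients from a precision matrix
#'
#' The coefficient of gene \eqn{k'} in the optimal linear regression of gene
#' \eqn{k} on all other genes is \eqn{b_{k'}^{(k)} = -\omega_{k'k} /
#' \omega_{kk}}. Returned as a matrix `b` with `b[kp, k]` the coefficient of
#' predictor `kp` in node `k`'s regression and a zero diagonal.
#'
#' @inheritParams partial_corr_from_precision
#' @return p x p matrix of coefficients, column k holding node k's regression.
#' @export
regression_coefs_from_precision <- function(omega) {
  omega <- check_precision(omega)
  b <- -sweep(omega, 2, diag(omega), "/")
  diag(b) <- 0
  b
}

#' Partial correlation from a coefficient pair
#'
#' Reconstructs the plug-in partial correlation from the two reciprocal
#' regression coefficients: \eqn{\rho = \mathrm{sign}(b_{k'}^{(k)})
#' \sqrt{b_{k'}^{(k)} b_k^{(k')}}} when the product is positive and 0
#' otherwise, clipped to \eqn{[-1, 1]}. With estimated (rather than exact)
#' coefficients the product can be negative or exceed 1, hence the zero rule
#' and the clipping.
#'
#' @param b_kp_k,b_k_kp The two coefficients (finite numerics, vectorized).
#' @return Clipped partial correlation(s) in \eqn{[-1, 1]}.
#' @export
pi_from_coef_pair <- function(b_kp_k, b_k_kp) {
  if (any(is.na(b_kp_k)) || any(is.na(b_k_kp)) ||
      any(!is.finite(b_kp_k)) || any(!is.finite(b_k_kp)))
    stop("coefficients must be finite and non-missing")
  prod <- b_kp_k * b_k_kp
  rho <- ifelse(prod > 0, sign(b_kp_k) * sqrt(pmax(prod, 0)), 0)
  pmin(pmax(rho, -1), 1)
}

#' Edge weights from a partial-correlation matrix
#'
#' Edge weights are absolute partial correlations,
#' \eqn{w_{k'k} = |\pi_{k'k}| \in [0, 1]} off the diagonal and 0 on it.
#'
#' @param pi_mat Symmetric partial-correlation matrix with entries in
#'   \eqn{[-1, 1]}.
#' @return Symmetric weighted adjacency matrix with entries in \eqn{[0, 1]}
#'   and zero diagonal.
#' @export
weights_from_partial_corr <- function(pi_mat) {
  if (!is.matrix(pi_mat) || nrow(pi_mat) != ncol(pi_mat))
    stop("'pi_mat' must be a square matrix")
  if (any(abs(pi_mat) > 1 + 1e-8))
    stop("partial correlations must lie in [-1, 1]")
  w <- abs(pi_mat)
  diag(w) <- 0
  w
}

## Plug-in weight matrix from a full coefficient matrix b (b[kp, k] =
## coefficient of predictor kp in node k's regression). Symmetric by
## construction of the sign rule.
weights_from_coefs <- function(b) {
  prod <- b * t(b)
  rho <- ifelse(prod > 0, sign(b) * sqrt(pmax(prod, 0)), 0)
  w <- abs(pmin(pmax(rho, -1), 1))
  diag(w) <- 0
  w
}
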