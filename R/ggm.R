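## Graph-constrained Gaussian maximum likelihood: covariance selection by the
## classical node-wise regression algorithm, Gaussian log-likelihood, EBIC
## scoring, and re-estimation of edge weights from the refit precision.

#' Sample covariance with divisor N
#'
#' \eqn{S = X^T X / N}: the maximum-likelihood covariance of a mean-zero
#' Gaussian model (divisor N, not N-1 — note a standardized column has
#' diagonal entry (N-1)/N, not 1).
#'
#' @param x Expression matrix (samples x genes), assumed mean-centered.
#' @return Symmetric p x p matrix with attribute `n` = sample count.
#' @export
sample_cov <- function(x) {
  s <- crossprod(x) / nrow(x)
  attr(s, "n") <- nrow(x)
  s
}

#' Gaussian log-likelihood of a precision matrix
#'
#' \eqn{l(\Omega) = \ln\det\Omega - \mathrm{tr}(S\Omega)}, the mean-zero
#' Gaussian log-likelihood per sample up to an additive constant (no N/2
#' factor).
#'
#' @param omega Symmetric positive-definite precision matrix.
#' @param s Sample covariance matrix.
#' @return Scalar log-likelihood.
#' @export
gaussian_loglik <- function(omega, s) {
  omega <- check_precision(omega)
  ch <- tryCatch(chol(omega), error = function(e)
    stop("'omega' is not positive definite"))
  2 * sum(log(diag(ch))) - sum(s * omega)
}

#' Maximum-likelihood precision matrix for a fixed graph
#'
#' Covariance selection: maximizes \eqn{l(\Omega) = \ln\det\Omega -
#' \mathrm{tr}(S\Omega)} over positive-definite matrices whose off-diagonal
#' support is restricted to the edges of `g`. Uses the classical node-wise
#' regression algorithm: cycle over nodes, solve the reduced linear system on
#' each node's neighbor set against the working covariance, and update that
#' row/column; at the stationary point the fitted covariance matches S on
#' every edge and on the diagonal.
#'
#' @param s Sample covariance (from [sample_cov()]).
#' @param g Graph: logical/0-1 p x p adjacency matrix (zero diagonal).
#' @param max_sweeps Maximum full cycles over the nodes.
#' @param tol Convergence threshold on the maximum change of the working
#'   covariance, relative to `mean(abs(diag(s)))`.
#' @return Positive-definite precision matrix with zeros on all non-edges,
#'   with attributes `sweeps` and `converged`.
#' @export
fit_precision_given_graph <- function(s, g, max_sweeps = 500, tol = 1e-8) {
  p <- nrow(s)
  adj <- (g != 0)
  diag(adj) <- FALSE
  adj <- adj | t(adj)
  if (!all(diag(s) > 0)) stop("sample covariance has non-positive diagonal")
  if (any(colSums(adj) >= attr(s, "n") %||% p) &&
      min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) < 1e-10 * max(diag(s)))
    warning("sample covariance is singular and the graph is dense; ",
            "the constrained MLE may not exist — returning the iterate at budget")

  w <- s                                   # working covariance
  betas <- vector("list", p)
  thr <- tol * mean(abs(diag(s)))
  converged <- FALSE
  sweeps <- 0
  for (sweeps in seq_len(max_sweeps)) {
    max_dw <- 0
    for (j in seq_len(p)) {
      ne <- which(adj[, j])
      if (length(ne) == 0) {
        new_col <- rep(0, p - 1)
        betas[[j]] <- numeric(0)
      } else {
        w11 <- w[ne, ne, drop = FALSE]
        bstar <- solve(w11, s[ne, j])
        betas[[j]] <- bstar
        new_col <- drop(w[-j, ne, drop = FALSE] %*% bstar)
      }
      max_dw <- max(max_dw, max(abs(w[-j, j] - new_col)))
      w[-j, j] <- new_col
      w[j, -j] <- new_col
    }
    if (max_dw < thr) { converged <- TRUE; break }
  }

  omega <- matrix(0, p, p, dimnames = dimnames(s))
  for (j in seq_len(p)) {
    ne <- which(adj[, j])
    bstar <- betas[[j]]
    o_jj <- 1 / (s[j, j] - if (length(ne)) sum(w[ne, j] * bstar) else 0)
    omega[j, j] <- o_jj
    if (length(ne)) omega[ne, j] <- -bstar * o_jj
  }
  omega <- (omega + t(omega)) / 2
  omega[!adj & row(omega) != col(omega)] <- 0
  if (!converged)
    warning("covariance selection did not converge within ", max_sweeps,
            " sweeps")
  attr(omega, "sweeps") <- sweeps
  attr(omega, "converged") <- converged
  omega
}

#' Extended BIC of a fitted precision matrix
#'
#' \eqn{\mathrm{EBIC}_\gamma(\hat\Omega) = -l(\hat\Omega) + \kappa (\ln N +
#' 4\gamma \ln p)/N}, where \eqn{\kappa} is the number of nonzero strict
#' upper-triangle entries (edges). \eqn{\gamma = 0} gives the ordinary BIC
#' scaling; positive \eqn{\gamma} adds the ln p penalty suited to p >> N
#' model selection.
#'
#' @param omega Fitted precision matrix.
#' @param s Sample covariance.
#' @param n Sample count.
#' @param p Gene count.
#' @param gamma EBIC parameter in \eqn{[0, 1]}.
#' @return List of class `"ebic_score"`: `loglik`, `kappa`, `ebic`, `gamma`.
#' @export
ebic_score <- function(omega, s, n = attr(s, "n"), p = nrow(s), gamma = 0) {
  if (gamma < 0 || gamma > 1) stop("'gamma' must lie in [0, 1]")
  ll <- gaussian_loglik(omega, s)
  kappa <- sum(omega[upper.tri(omega)] != 0)
  structure(list(loglik = ll, kappa = kappa,
                 ebic = -ll + kappa * (log(n) + 4 * gamma * log(p)) / n,
                 gamma = gamma),
            class = "ebic_score")
}

#' Re-estimate edge weights from a refit precision matrix
#'
#' Absolute partial correlations of the graph-constrained ML precision:
#' zero exactly where the precision is zero.
#'
#' @param omega_hat Fitted precision matrix.
#' @return Weighted adjacency matrix.
#' @export
reestimate_weights <- function(omega_hat) {
  w <- weights_from_partial_corr(partial_corr_from_precision(omega_hat))
  w[omega_hat == 0] <- 0
  diag(w) <- 0
  w
}
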