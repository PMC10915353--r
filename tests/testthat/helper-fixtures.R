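## Shared fixture builders; everything is generated in code under fixed seeds.

# random symmetric positive-definite matrix with eigenvalues bounded away
# from zero
random_spd <- function(p, jitter = 0.5) {
  m <- matrix(rnorm(p * p), p, p)
  crossprod(m) / p + jitter * diag(p)
}

# expression fixture with two tight co-expression blocks around core genes
# plus independent background genes
block_fixture <- function(n = 80, block_size = 8, n_blocks = 2, n_noise = 6,
                          rho = 0.8, seed = 42) {
  set.seed(seed)
  cores <- paste0("core", seq_len(n_blocks))
  cols <- list()
  for (b in seq_len(n_blocks)) {
    z <- rnorm(n)
    block <- sapply(seq_len(block_size - 1), function(j)
      rho * z + sqrt(1 - rho^2) * rnorm(n))
    colnames(block) <- paste0("b", b, "m", seq_len(block_size - 1))
    m <- cbind(z, block)
    colnames(m)[1] <- cores[b]
    cols[[b]] <- m
  }
  noise <- matrix(rnorm(n * n_noise), nrow = n, ncol = n_noise,
                  dimnames = list(NULL,
                                  if (n_noise > 0) paste0("noise", seq_len(n_noise))))
  x <- do.call(cbind, c(cols, if (n_noise > 0) list(noise)))
  rownames(x) <- paste0("s", seq_len(n))
  list(x = x, cores = cores,
       members = lapply(seq_len(n_blocks), function(b)
         colnames(cols[[b]])[-1]))
}

# brute-force graph-constrained Gaussian ML by numerical optimization over
# the free entries of the precision matrix (oracle for small p)
constrained_mle_oracle <- function(s, adj, omega0 = NULL) {
  p <- nrow(s)
  free <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  pack <- function(om) c(log(diag(om)), om[free])
  unpack <- function(par) {
    om <- matrix(0, p, p)
    diag(om) <- exp(par[seq_len(p)])
    if (nrow(free) > 0) {
      om[free] <- par[-seq_len(p)]
      om[free[, c(2, 1), drop = FALSE]] <- par[-seq_len(p)]
    }
    om
  }
  nll <- function(par) {
    om <- unpack(par)
    ch <- tryCatch(chol(om), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    -(2 * sum(log(diag(ch))) - sum(s * om))
  }
  om0 <- if (is.null(omega0)) diag(1 / diag(s)) else omega0
  fit <- optim(pack(om0), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  unpack(fit$par)
}
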