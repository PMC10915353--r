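## Simulation of hub gene networks, their precision matrices, and Gaussian
## expression samples; plus small fixture generators used throughout the
## tests.

## Run `expr` under a temporary RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards; with seed = NULL the global stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a hub gene network
#'
#' Generates an undirected simple graph on `p` genes with `n_hubs` hub nodes.
#' Each hub is attached to every other node independently with probability
#' `hub_mean_degree / (p - 1)`; background edges between non-hub pairs are
#' added with the probability that brings the expected non-hub degree
#' (including its hub attachments) to `nonhub_mean_degree`. At the defaults
#' (p = 100, 4 hubs, hub degree ~32, non-hub degree ~2) the resulting graphs
#' have sparsity level about 0.97 and degree centralization about 0.33.
#'
#' @param p Number of genes.
#' @param n_hubs Number of hub genes (0 gives a plain sparse background
#'   graph).
#' @param hub_mean_degree Target mean degree of a hub node.
#' @param nonhub_mean_degree Target mean degree of a non-hub node.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Logical p x p adjacency matrix with gene dimnames `g1..gp` and
#'   attribute `hubs` (character vector of hub gene ids).
#' @export
simulate_hub_graph <- function(p = 100, n_hubs = 4, hub_mean_degree = 32,
                               nonhub_mean_degree = 2, seed = NULL) {
  if (n_hubs >= p) stop("'n_hubs' must be smaller than 'p'")
  if (hub_mean_degree > p - 1) stop("'hub_mean_degree' cannot exceed p - 1")
  with_seed(seed, {
    genes <- paste0("g", seq_len(p))
    hubs <- if (n_hubs > 0) sort(sample.int(p, n_hubs)) else integer(0)
    is_hub <- seq_len(p) %in% hubs
    p_hub <- hub_mean_degree / (p - 1)
    # expected non-hub degree contributed by hub attachments
    from_hubs <- n_hubs * p_hub
    n_nonhub <- p - n_hubs
    p_bg <- if (n_nonhub > 1)
      max(0, nonhub_mean_degree - from_hubs) / (n_nonhub - 1) else 0
    adj <- matrix(FALSE, p, p, dimnames = list(genes, genes))
    ut <- which(upper.tri(adj), arr.ind = TRUE)
    touches_hub <- is_hub[ut[, 1]] | is_hub[ut[, 2]]
    prob <- ifelse(touches_hub, p_hub, p_bg)
    edge <- runif(nrow(ut)) < prob
    adj[ut[edge, , drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    attr(adj, "hubs") <- genes[hubs]
    adj
  })
}

#' Precision matrix of a simulated graph
#'
#' \eqn{\Omega = A + (0.1 - \Lambda_{\min}(A)) I}, where A is the 0/1
#' adjacency matrix: a positive-definite precision whose smallest eigenvalue
#' is exactly 0.1 and whose off-diagonal support is the graph.
#'
#' @param g Adjacency matrix (logical or 0/1).
#' @return Symmetric positive-definite precision matrix.
#' @export
precision_from_graph <- function(g) {
  a <- (g != 0) * 1
  diag(a) <- 0
  lam_min <- min(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
  omega <- a
  diag(omega) <- 0.1 - lam_min
  dimnames(omega) <- dimnames(g) %||% NULL
  omega
}

#' Sample Gaussian expression data from a precision matrix
#'
#' Draws `n` i.i.d. samples from \eqn{N_p(0, \Omega^{-1})}.
#'
#' @param omega Symmetric positive-definite precision matrix.
#' @param n Number of samples.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return n x p expression matrix (colnames from `omega`).
#' @export
sample_expression <- function(omega, n = 60, seed = NULL) {
  omega <- check_precision(omega)
  p <- ncol(omega)
  # X = Z R^{-1} with omega = R'R gives Cov(X) = (R'R)^{-1} = omega^{-1}
  r <- chol(omega)
  with_seed(seed, {
    z <- matrix(rnorm(n * p), n, p)
    x <- t(backsolve(r, t(z)))
    colnames(x) <- colnames(omega)
    rownames(x) <- paste0("s", seq_len(n))
    x
  })
}

#' Simulate a complete hub-network study dataset
#'
#' Convenience wrapper: hub graph, its precision matrix, and N Gaussian
#' expression samples, as used in the benchmark experiments.
#'
#' @inheritParams simulate_hub_graph
#' @param n Number of expression samples (the study default is 60).
#' @return List with `graph` (adjacency), `hubs`, `omega`, `x` (expression).
#' @export
simulate_hub_gn <- function(p = 100, n_hubs = 4, n = 60, hub_mean_degree = 32,
                            nonhub_mean_degree = 2, seed = NULL) {
  with_seed(seed, {
    g <- simulate_hub_graph(p, n_hubs, hub_mean_degree, nonhub_mean_degree)
    omega <- precision_from_graph(g)
    x <- sample_expression(omega, n)
    list(graph = g, hubs = attr(g, "hubs"), omega = omega, x = x)
  })
}

#' Null expression data with independent genes
#'
#' @param n,p Samples and genes.
#' @param seed Optional integer seed.
#' @return n x p matrix of independent standard normal columns.
#' @export
simulate_null_data <- function(n = 200, p = 10, seed = NULL) {
  with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("s", seq_len(n)), paste0("g", seq_len(p))))
    x
  })
}

#' Chain-graph expression data
#'
#' Data from the Gaussian graphical model of a path graph 1-2-...-p, a small
#' structured fixture.
#'
#' @param n,p Samples and genes.
#' @param seed Optional integer seed.
#' @return List with `graph`, `omega`, `x`.
#' @export
simulate_chain_data <- function(n = 100, p = 5, seed = NULL) {
  genes <- paste0("g", seq_len(p))
  adj <- matrix(FALSE, p, p, dimnames = list(genes, genes))
  for (j in seq_len(p - 1)) adj[j, j + 1] <- adj[j + 1, j] <- TRUE
  omega <- precision_from_graph(adj)
  list(graph = adj, omega = omega, x = sample_expression(omega, n, seed = seed))
}
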