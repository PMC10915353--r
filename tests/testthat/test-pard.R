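test_that("standardization centers, scales, reports offenders and is idempotent", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 20, 40))
  s <- standardize_expression(x)
  expect_equal(unname(s[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(s), c(a = 0, b = 0))
  expect_equal(apply(s, 2, sd), c(a = 1, b = 1))
  expect_lt(max(abs(standardize_expression(s) - s)), 1e-12)

  two <- cbind(g = c(10, 20))
  expect_equal(unname(standardize_expression(two)[, 1]),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)

  const <- cbind(a = c(1, 2, 3), flat = c(5, 5, 5))
  expect_error(standardize_expression(const), "flat")
})

test_that("ridge posterior solves the penalized normal equations", {
  # closed-form 2 x 2 case: (X'X + alpha/beta) b = X'y with X'X = 2, X'y = 3
  x <- cbind(g1 = c(1, 2), g2 = c(1, 1))
  out <- ridge_posterior(x, k = 1, alpha_k = 1, beta = 1)
  expect_equal(unname(out$b), 1)
  expect_equal(out$post_cov, matrix(1 / 3), ignore_attr = TRUE)

  set.seed(5)
  x <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("g", 1:4)))
  # infinite-shrinkage limit
  big <- ridge_posterior(x, 2, rep(1e12, 3), beta = 1)
  expect_lt(max(abs(big$b)), 1e-6)
  # zero-penalty limit recovers least squares
  ols <- coef(lm(x[, 2] ~ x[, -2] - 1))
  small <- ridge_posterior(x, 2, rep(1e-12, 3), beta = 1)
  expect_equal(unname(small$b), unname(ols), tolerance = 1e-6)
  expect_error(ridge_posterior(x, 1, rep(-1, 3), 1), "positive")
})

test_that("log marginal likelihood matches the direct Gaussian evidence", {
  # degenerate single-sample case: standard normal density at zero
  x0 <- matrix(0, 1, 2)
  expect_equal(log_marginal_likelihood(x0, 1, alpha_k = 2, beta = 1),
               -0.5 * log(2 * pi))

  # Woodbury computation vs direct N x N covariance evaluation
  set.seed(9)
  x <- matrix(rnorm(60), 12, 5)
  alpha_k <- runif(4, 0.2, 5)
  beta <- 1.7
  direct <- {
    xk <- x[, -3]
    cov_n <- diag(12) / beta + xk %*% diag(1 / alpha_k) %*% t(xk)
    -0.5 * (12 * log(2 * pi) + determinant(cov_n)$modulus[1] +
              drop(x[, 3] %*% solve(cov_n, x[, 3])))
  }
  expect_equal(log_marginal_likelihood(x, 3, alpha_k, beta), direct,
               tolerance = 1e-8)
})

test_that("evidence has a finite interior maximum in beta", {
  set.seed(10)
  x <- standardize_expression(matrix(rnorm(100), 20, 5))
  betas <- 10^seq(-4, 6, length.out = 60)
  ev <- vapply(betas, function(b)
    log_marginal_likelihood(x, 1, rep(1, 4), b), numeric(1))
  i <- which.max(ev)
  expect_gt(i, 1)
  expect_lt(i, length(ev))
})

test_that("the pARD objective combines evidence and Gamma priors", {
  set.seed(12)
  x <- standardize_expression(matrix(rnorm(60), 15, 4))
  theta <- pard_hyperparams(4, s = 2, r = 0.5, s_beta = 1, r_beta = 1)
  st <- list(alpha = matrix(1.3, 4, 4), beta = 0.8)
  obj <- pard_objective(x, st, theta)
  expect_true(is.finite(obj))
  # independent recomputation with stats::dgamma
  manual <- 0
  for (k in 1:4) {
    manual <- manual + log_marginal_likelihood(x, k, rep(1.3, 3), 0.8) +
      sum(dgamma(rep(1.3, 3), shape = 2, rate = 0.5, log = TRUE)) +
      dgamma(0.8, shape = 1, rate = 1, log = TRUE)
  }
  expect_equal(obj, manual, tolerance = 1e-10)
  expect_error(pard_objective(x, list(alpha = st$alpha, beta = -1), theta),
               "positive")
})

test_that("pARD determines relevance on constructed collinear data", {
  set.seed(21)
  n <- 120
  x1 <- rnorm(n)
  x <- cbind(g1 = x1, g2 = x1 + 0.1 * rnorm(n), g3 = rnorm(n))
  fit <- fit_pard(standardize_expression(x))
  # in node 1's regression, the irrelevant predictor g3 is pruned much
  # harder than the informative g2
  expect_gt(fit$alpha["g3", "g1"] / fit$alpha["g2", "g1"], 10)
  expect_gt(abs(fit$b["g2", "g1"]), abs(fit$b["g3", "g1"]))
})

test_that("pARD shrinks all coefficients on independent data", {
  x <- standardize_expression(simulate_null_data(200, 5, seed = 31))
  fit <- fit_pard(x)
  # every coefficient stays small and is shrunk relative to least squares
  expect_lt(max(abs(fit$b)), 0.2)
  ols_max <- max(vapply(1:5, function(k)
    max(abs(coef(lm(x[, k] ~ x[, -k] - 1)))), numeric(1)))
  expect_lte(max(abs(fit$b)), ols_max + 1e-12)
  expect_true(fit$converged)
})

test_that("returned coefficients are the exact ridge solution at the returned precisions", {
  x <- standardize_expression(simulate_null_data(40, 6, seed = 8))
  fit <- fit_pard(x)
  expect_length(fit$beta, 1)         # one shared noise precision
  for (k in c(1, 4, 6)) {
    rp <- ridge_posterior(x, k, fit$alpha[-k, k], fit$beta)
    expect_equal(unname(fit$b[-k, k]), unname(rp$b), tolerance = 1e-10)
  }
})

test_that("stronger prior rates never increase coefficient magnitudes", {
  x <- standardize_expression(simulate_null_data(50, 4, seed = 14))
  sizes <- vapply(c(0.5, 2, 8, 32), function(r0) {
    fit <- fit_pard(x, pard_hyperparams(4, s = r0^2, r = r0))
    max(abs(fit$b))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 1e-10))
})

test_that("fixed-point objective improves on the initial state in most trials", {
  wins <- 0
  for (i in 1:10) {
    x <- standardize_expression(simulate_null_data(30, 4, seed = 100 + i))
    theta <- pard_hyperparams(4, s = 4, r = 2)
    init <- list(alpha = matrix(1, 4, 4), beta = 1)
    obj0 <- pard_objective(x, init, theta)
    fit <- fit_pard(x, theta, compute_objective = TRUE)
    if (fit$objective_value >= obj0 - 1e-8) wins <- wins + 1
  }
  expect_gte(wins, 9)
})
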