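test_that("sample covariance uses divisor N on mean-zero data", {
  x <- rbind(c(1, 0), c(0, 1))
  expect_equal(unname(sample_cov(x)), diag(2) / 2, ignore_attr = TRUE)

  set.seed(6)
  xs <- standardize_expression(matrix(rnorm(50), 10, 5))
  s <- sample_cov(xs)
  expect_equal(unname(diag(s)), rep(9 / 10, 5))   # sd uses N-1, S uses N
  expect_true(isSymmetric(s))
  expect_gte(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), -1e-12)
})

test_that("Gaussian log-likelihood matches closed forms and is maximized at S^-1", {
  set.seed(7)
  x <- matrix(rnorm(200), 40, 5)
  s <- sample_cov(x)
  expect_equal(gaussian_loglik(diag(5), s), -sum(diag(s)))
  expect_equal(gaussian_loglik(solve(s), s),
               -determinant(s)$modulus[1] - 5, ignore_attr = TRUE)
  for (i in 1:5) {
    om <- random_spd(5)
    expect_lte(gaussian_loglik(om, s), gaussian_loglik(solve(s), s) + 1e-10)
  }
})

test_that("graph-constrained MLE hits closed forms for empty and complete graphs", {
  set.seed(8)
  x <- matrix(rnorm(300), 60, 5)
  s <- sample_cov(x)
  empty <- matrix(FALSE, 5, 5)
  om_empty <- fit_precision_given_graph(s, empty)
  expect_equal(unname(om_empty), diag(1 / diag(s)), ignore_attr = TRUE)
  complete <- !diag(5)
  om_full <- fit_precision_given_graph(s, complete)
  expect_equal(unname(om_full), unname(solve(s)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("graph-constrained MLE satisfies stationarity and matches brute force", {
  set.seed(9)
  x <- matrix(rnorm(240), 40, 6)
  s <- sample_cov(x)
  adj <- matrix(FALSE, 6, 6)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 5), c(5, 6))
  for (i in seq_len(nrow(edges)))
    adj[edges[i, 1], edges[i, 2]] <- adj[edges[i, 2], edges[i, 1]] <- TRUE

  om <- fit_precision_given_graph(s, adj)
  # zeros exactly on non-edges
  expect_true(all(om[!adj & !diag(6)] == 0))
  # fitted covariance matches S on edges and diagonal
  sig <- solve(om)
  expect_lt(max(abs(sig[adj] - s[adj])), 1e-6)
  expect_lt(max(abs(diag(sig) - diag(s))), 1e-6)
  # likelihood agrees with a generic numerical maximizer of the free entries
  oracle <- constrained_mle_oracle(s, adj, om)
  expect_equal(gaussian_loglik(om, s), gaussian_loglik(oracle, s),
               tolerance = 1e-5)
})

test_that("likelihood is monotone over nested graphs and refits are idempotent", {
  set.seed(10)
  x <- matrix(rnorm(200), 40, 5)
  s <- sample_cov(x)
  g1 <- matrix(FALSE, 5, 5)
  g1[1, 2] <- g1[2, 1] <- TRUE
  g2 <- g1
  g2[2, 3] <- g2[3, 2] <- g2[4, 5] <- g2[5, 4] <- TRUE
  l1 <- gaussian_loglik(fit_precision_given_graph(s, g1), s)
  l2 <- gaussian_loglik(fit_precision_given_graph(s, g2), s)
  expect_lte(l1, l2 + 1e-10)

  om2 <- fit_precision_given_graph(s, g2)
  again <- fit_precision_given_graph(s, om2 != 0 & !diag(5))
  expect_equal(om2, again, tolerance = 1e-7, ignore_attr = TRUE)
})

test_that("EBIC scoring counts upper-triangle edges and penalizes them", {
  set.seed(11)
  x <- matrix(rnorm(150), 30, 5)
  s <- sample_cov(x)
  om_diag <- diag(1 / diag(s))
  sc0 <- ebic_score(om_diag, s, n = 30, p = 5, gamma = 0.2)
  expect_equal(sc0$kappa, 0)
  expect_equal(sc0$ebic, -sc0$loglik)

  g <- matrix(FALSE, 5, 5); g[1, 2] <- g[2, 1] <- TRUE
  om1 <- fit_precision_given_graph(s, g)
  sc1 <- ebic_score(om1, s, n = 30, p = 5, gamma = 0)
  expect_equal(sc1$kappa, 1)
  # gamma = 0 penalty per edge is log(N)/N
  expect_equal(sc1$ebic, -sc1$loglik + log(30) / 30)
  # an edge with negligible likelihood gain raises the EBIC
  sc1_pen <- ebic_score(om1, s, n = 30, p = 5, gamma = 0.2)
  expect_gt(sc1_pen$ebic - (-sc1_pen$loglik), 0)
  expect_error(ebic_score(om1, s, gamma = 2), "gamma")
})

test_that("re-estimated weights share the refit support", {
  set.seed(12)
  x <- matrix(rnorm(240), 40, 6)
  s <- sample_cov(x)
  expect_equal(reestimate_weights(diag(1 / diag(s))), matrix(0, 6, 6),
               ignore_attr = TRUE)
  adj <- matrix(FALSE, 6, 6)
  adj[1, 2] <- adj[2, 1] <- adj[3, 4] <- adj[4, 3] <- TRUE
  om <- fit_precision_given_graph(s, adj)
  w <- reestimate_weights(om)
  expect_true(all(w[!adj] == 0))
  expect_true(all(w[adj] > 0))
  # complete graph reduces to the partial correlations of S^-1
  om_full <- fit_precision_given_graph(s, !diag(6))
  expect_equal(reestimate_weights(om_full),
               weights_from_partial_corr(partial_corr_from_precision(om_full)))
})
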