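test_that("connectivity is the column mean of the weight matrix", {
  expect_equal(connectivity(matrix(0, 3, 3)), rep(0, 3))
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.6
  expect_equal(connectivity(w), c(0.2, 0.2, 0))
  set.seed(2)
  w <- weights_from_partial_corr(partial_corr_from_precision(random_spd(8)))
  expect_true(all(connectivity(w) <= (8 - 1) / 8))
})

test_that("hyper-rate update follows the reciprocal drive with squared shapes", {
  cfg <- apard_control(lam = 1, xi = 0, phi = function(t) t + 0.01)
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.99
  out <- update_hyperrates(w, connectivity(w), cfg)
  expect_equal(out$r[1, 2], 1 / 1.00 + 0.5)
  expect_equal(out$s[1, 2], 1.5^2)
  expect_true(all(out$s[row(out$s) != col(out$s)] > 0.25))

  # raising a weight strictly lowers its rate (xi = 0)
  w2 <- w; w2[1, 2] <- w2[2, 1] <- 0.5
  out2 <- update_hyperrates(w2, connectivity(w2), cfg)
  expect_gt(out2$r[1, 2], out$r[1, 2])

  # xi = 1: rate for predictor k' identical across target nodes
  cfg1 <- apard_control(lam = 2, xi = 1)
  set.seed(4)
  w3 <- weights_from_partial_corr(partial_corr_from_precision(random_spd(5)))
  out3 <- update_hyperrates(w3, connectivity(w3), cfg1)
  for (kp in 1:5) {
    vals <- out3$r[kp, -kp]
    expect_lt(diff(range(vals)), 1e-12)
  }
})

test_that("hub prior edge sets contain exactly the hub-touching pairs", {
  genes <- paste0("g", 1:4)
  e0 <- hub_prior_edges(genes, "g1")
  expect_equal(sum(e0) / 2, 3)
  expect_true(all(e0["g1", -1]))
  expect_false(any(e0[2:4, 2:4]))

  expect_equal(sum(hub_prior_edges(genes, genes)) / 2, 6)
  expect_equal(sum(hub_prior_edges(genes, character(0))), 0)
  expect_error(hub_prior_edges(genes, "g9"), "g9")
})

test_that("prior-graph shrinkage scales only non-prior pairs", {
  genes <- paste0("g", 1:4)
  w <- matrix(0.5, 4, 4, dimnames = list(genes, genes))
  diag(w) <- 0
  e0 <- hub_prior_edges(genes, "g1")

  z <- apply_prior_graph_shrinkage(w, e0, 0)
  expect_equal(z["g1", "g2"], 0.5)
  expect_equal(z["g2", "g3"], 0)

  s <- apply_prior_graph_shrinkage(w, e0, 0.2)
  expect_equal(s["g2", "g3"], 0.1)
  expect_equal(s["g1", "g4"], 0.5)

  all_pairs <- hub_prior_edges(genes, genes)
  expect_equal(apply_prior_graph_shrinkage(w, all_pairs, 0), w)

  bad <- cbind(gene_a = "g1", gene_b = "g9")
  expect_error(apply_prior_graph_shrinkage(w, bad, 0.5), "g9")
})

test_that("hub-constrained adaptive fit with zero shrinkage is bipartite-restricted", {
  sim <- simulate_hub_gn(p = 15, n_hubs = 2, n = 50, hub_mean_degree = 6,
                         seed = 17)
  x <- standardize_expression(sim$x)
  e0 <- hub_prior_edges(colnames(x), sim$hubs)
  af <- fit_apard(x, apard_control(lam = 2, c_shrink = 0, prior_edges = e0))
  non_hub <- setdiff(colnames(x), sim$hubs)
  expect_equal(sum(af$w[non_hub, non_hub]), 0)
  # prior pairs are untouched by shrinkage, so some hub edges survive
  expect_gt(sum(af$adjacency) / 2, 0)
  expect_true(all(af$adjacency[non_hub, non_hub] == FALSE))
})

test_that("adaptive fit prunes independent data to almost nothing", {
  x <- standardize_expression(simulate_null_data(200, 10, seed = 23))
  af <- fit_apard(x, apard_control(lam = 200, xi = 0))
  expect_lte(sum(af$adjacency[upper.tri(af$adjacency)]), 2)
})

test_that("adaptive fit output is symmetric, thresholded and deterministic", {
  sim <- simulate_hub_gn(p = 12, n_hubs = 1, n = 40, hub_mean_degree = 5,
                         seed = 5)
  x <- standardize_expression(sim$x)
  af <- fit_apard(x, apard_control(lam = 3))
  expect_true(isSymmetric(af$w))
  expect_equal(diag(af$w), setNames(rep(0, 12), colnames(x)))
  surviving <- af$w[af$w > 0]
  if (length(surviving) > 0) expect_true(all(surviving >= 1e-3))
  af2 <- fit_apard(x, apard_control(lam = 3))
  expect_identical(af$w, af2$w)
})

test_that("larger lambda does not produce denser graphs", {
  sim <- simulate_hub_gn(p = 12, n_hubs = 1, n = 40, hub_mean_degree = 5,
                         seed = 29)
  x <- standardize_expression(sim$x)
  zeros <- vapply(c(1, 4, 16, 64), function(l)
    sum(fit_apard(x, apard_control(lam = l))$w == 0), numeric(1))
  violations <- sum(diff(zeros) < 0)
  expect_lte(violations, 1)
})
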