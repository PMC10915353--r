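test_that("co-expression distance is sign-blind and bounded", {
  set.seed(1)
  z <- rnorm(50)
  x <- cbind(a = z, b = 2 * z + 1, c = -z, d = rnorm(50))
  d <- coexpression_distance(x)
  expect_equal(d["a", "b"], 0, tolerance = 1e-12)
  expect_equal(d["a", "c"], 0, tolerance = 1e-12)  # anti-correlation
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(diag(d), setNames(rep(0, 4), colnames(x)))

  set.seed(2)
  big <- cbind(u = rnorm(1000), v = rnorm(1000), w = rnorm(1000))
  dd <- coexpression_distance(big)
  expect_lt(abs(dd["u", "v"] - 1), 0.08)

  xc <- cbind(a = rnorm(10), flat = rep(1, 10))
  expect_error(coexpression_distance(xc), "flat")
})

test_that("tree cut recovers well-separated co-expression blocks", {
  fx <- block_fixture(n = 80, block_size = 20, n_blocks = 2, n_noise = 0,
                      rho = 0.85, seed = 9)
  d <- coexpression_distance(fx$x)
  for (linkage in c("average", "complete", "ward")) {
    cl <- hierarchical_clusters(d, linkage = linkage, min_cluster_size = 5)
    expect_equal(cl$n_clusters, 2)
    expect_equal(sum(cl$labels == 0), 0)
    # each block is one cluster
    lab1 <- cl$labels[c(fx$cores[1], fx$members[[1]])]
    expect_length(unique(lab1), 1)
  }
})

test_that("degenerate and permuted cuts behave predictably", {
  fx <- block_fixture(n = 60, block_size = 10, n_blocks = 2, n_noise = 4,
                      seed = 10)
  d <- coexpression_distance(fx$x)
  p <- ncol(d)

  cl_all <- hierarchical_clusters(d, min_cluster_size = p)
  expect_lte(cl_all$n_clusters, 1)      # one cluster or everything noise

  expect_error(hierarchical_clusters(d, min_cluster_size = p + 1),
               "min_cluster_size")

  cl <- hierarchical_clusters(d, min_cluster_size = 5)
  set.seed(11)
  perm <- sample(p)
  cl_perm <- hierarchical_clusters(d[perm, perm], min_cluster_size = 5)
  # same partition up to label names
  part <- split(names(cl$labels), cl$labels)
  part_perm <- split(names(cl_perm$labels), cl_perm$labels)
  canon <- function(pp) unname(lapply(pp, sort)[order(sapply(pp, function(g)
    sort(g)[1]))])
  expect_equal(canon(part), canon(part_perm))
})

test_that("core clusters are the non-noise clusters containing core genes", {
  labels <- setNames(c(1, 1, 1, 2, 2, 2, 0, 0), paste0("g", 1:8))
  assign <- structure(list(labels = labels, n_clusters = 2),
                      class = "cluster_assignment")
  sel <- select_core_clusters(assign, c("g1", "g7"))
  expect_length(sel, 1)                  # g7 is noise, only cluster 1 counts
  expect_equal(sel[[1]]$core_genes, "g1")

  sel_all <- select_core_clusters(assign, c("g1", "g4"))
  expect_length(sel_all, 2)
  expect_length(select_core_clusters(assign, "g8"), 0)
})

test_that("core-network extension recovers planted hub-member structure", {
  fx <- block_fixture(n = 80, block_size = 8, n_blocks = 3, n_noise = 6,
                      rho = 0.8, seed = 12)
  core <- data.frame(gene_a = fx$cores[c(1, 2)], gene_b = fx$cores[c(2, 3)])
  ext <- suppressWarnings(
    extend_core_gn(fx$x, core, min_cluster_size = 5, c_shrink = 0,
                   n_lambda = 6))

  # core edges always preserved
  core_keys <- c("core1 core2", "core2 core3")
  got <- paste(ext$edges$gene_a, ext$edges$gene_b)
  expect_true(all(core_keys %in% got))

  # with zero shrinkage every inferred edge touches a core gene
  inf <- ext$edges[ext$edges$source == "inferred", ]
  expect_true(all(inf$gene_a %in% fx$cores | inf$gene_b %in% fx$cores))

  # planted recall: most core-member pairs are recovered
  planted <- unlist(lapply(1:3, function(b)
    paste(pmin(fx$cores[b], fx$members[[b]]),
          pmax(fx$cores[b], fx$members[[b]]))))
  recall <- mean(planted %in% got)
  expect_gte(recall, 0.8)
})

test_that("an empty or unmatched core network yields an empty extension", {
  fx <- block_fixture(seed = 13)
  core0 <- data.frame(gene_a = character(0), gene_b = character(0))
  ext0 <- extend_core_gn(fx$x, core0)
  expect_equal(nrow(ext0$edges), 0)
  expect_length(ext0$genes, 0)

  core_bad <- data.frame(gene_a = "nope1", gene_b = "nope2")
  expect_warning(ext_bad <- extend_core_gn(fx$x, core_bad), "dropped")
  expect_equal(nrow(ext_bad$edges), 0)
})
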