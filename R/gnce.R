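## Co-expression extension of a core gene network: cluster genes by absolute
## correlation, pick clusters containing core-network genes, infer each
## cluster's network with the core genes as hubs, and merge the inferred
## interactions into the core network.

#' Co-expression distance matrix
#'
#' \eqn{d_{k'k} = 1 - |\mathrm{Corr}(X^{(k')}, X^{(k)})|}: sign-blind, so
#' strongly anti-correlated genes are close too.
#'
#' @param x Expression matrix (samples x genes), at least 3 samples.
#' @return Symmetric p x p distance matrix with zero diagonal.
#' @export
coexpression_distance <- function(x) {
  if (nrow(x) < 3) stop("need at least 3 samples")
  s <- apply(x, 2, sd)
  if (any(s == 0)) {
    bad <- colnames(x)[s == 0] %||% which(s == 0)
    stop("constant gene(s): ", paste(bad, collapse = ", "))
  }
  d <- 1 - abs(cor(x))
  diag(d) <- 0
  d[d < 0] <- 0
  d
}

#' Cut a co-expression dendrogram into clusters
#'
#' Agglomerative clustering of the distance matrix followed by an adaptive
#' tree cut: the dendrogram is cut at `cut_height` (by default a fraction of
#' the top merge height controlled by `deep_split`; larger `deep_split` cuts
#' lower, giving more, smaller clusters), branches of at least
#' `min_cluster_size` genes become clusters, and each remaining gene is
#' assigned to the cluster with the smallest average distance provided that
#' distance does not exceed the cut height; genes left over form the noise
#' cluster, label 0. `method = "height"` skips the size filtering and
#' reassignment and returns the plain fixed-height cut.
#'
#' @param d Distance matrix (e.g. from [coexpression_distance()]).
#' @param linkage One of `"average"`, `"complete"`, `"ward"` (Ward.D2).
#' @param min_cluster_size Minimum size of a non-noise cluster.
#' @param method `"hybrid"` (adaptive, default) or `"height"` (plain cut).
#' @param cut_height Absolute cut height; default derived from `deep_split`.
#' @param deep_split Integer 0-4 controlling the default cut height.
#' @return List of class `"cluster_assignment"`: `labels` (named integer
#'   vector, 0 = noise, clusters numbered by decreasing size) and
#'   `n_clusters`.
#' @export
hierarchical_clusters <- function(d, linkage = c("average", "complete",
                                                 "ward"),
                                  min_cluster_size = 10,
                                  method = c("hybrid", "height"),
                                  cut_height = NULL, deep_split = 2) {
  linkage <- match.arg(linkage)
  method <- match.arg(method)
  p <- nrow(d)
  if (min_cluster_size > p) stop("'min_cluster_size' exceeds the gene count")
  genes <- colnames(d) %||% paste0("g", seq_len(p))
  hc <- hclust(as.dist(d), method = switch(linkage, ward = "ward.D2",
                                           linkage))
  h_max <- max(hc$height)
  if (is.null(cut_height)) {
    if (deep_split < 0 || deep_split > 4) stop("'deep_split' must be in 0..4")
    cut_height <- (0.99 - 0.05 * deep_split) * h_max
  }
  raw <- cutree(hc, h = min(cut_height, h_max))
  names(raw) <- genes

  if (method == "height") {
    sizes <- sort(table(raw), decreasing = TRUE)
    relab <- setNames(seq_along(sizes), names(sizes))
    labels <- as.integer(relab[as.character(raw)])
    names(labels) <- genes
    return(structure(list(labels = labels, n_clusters = length(sizes)),
                     class = "cluster_assignment"))
  }

  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_cluster_size]
  keep <- keep[order(-sizes[keep])]
  labels <- integer(p)
  names(labels) <- genes
  for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- i

  # reassign leftover genes to the nearest retained cluster when close enough
  if (length(keep) > 0) {
    loose <- which(labels == 0)
    for (g in loose) {
      avg <- vapply(seq_along(keep), function(i)
        mean(d[g, labels == i & seq_len(p) != g]), numeric(1))
      i_min <- which.min(avg)
      if (avg[i_min] <= cut_height) labels[g] <- i_min
    }
  }
  structure(list(labels = labels, n_clusters = length(keep)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster assignment:", x$n_clusters, "cluster(s),",
      sum(x$labels == 0), "noise gene(s)\n")
  invisible(x)
}

## Normalize a core network edge specification to a canonical data frame.
core_edges_df <- function(core) {
  if (is.matrix(core)) core <- as.data.frame(core, stringsAsFactors = FALSE)
  if (!is.data.frame(core) || ncol(core) < 2)
    stop("'core' must be a two-column edge list")
  e <- data.frame(gene_a = as.character(core[[1]]),
                  gene_b = as.character(core[[2]]),
                  stringsAsFactors = FALSE)
  swap <- e$gene_a > e$gene_b
  e[swap, c("gene_a", "gene_b")] <- e[swap, c("gene_b", "gene_a")]
  e <- e[e$gene_a != e$gene_b, , drop = FALSE]
  unique(e)
}

#' Select clusters containing core-network genes
#'
#' @param assign A `"cluster_assignment"`.
#' @param core_genes Character vector of core-network gene ids.
#' @return List, one element per selected (non-noise) cluster, each with
#'   `cluster` (label), `members`, `core_genes`.
#' @export
select_core_clusters <- function(assign, core_genes) {
  labels <- assign$labels
  out <- list()
  for (i in seq_len(assign$n_clusters)) {
    members <- names(labels)[labels == i]
    hit <- intersect(core_genes, members)
    if (length(hit) > 0)
      out[[length(out) + 1]] <- list(cluster = i, members = members,
                                     core_genes = hit)
  }
  out
}

#' Extend a core gene network through co-expressed genes
#'
#' The full co-expression extension pipeline: cluster all genes by
#' \eqn{1 - |\mathrm{Corr}|} distance, select the clusters containing at
#' least one core-network gene, infer each selected cluster's network with
#' [netard()] using the contained core genes as hubs (NetARD_H, \eqn{\xi=0}),
#' and merge the inferred edges into the core network. Core edges are always
#' preserved; with `c_shrink = 0` every inferred edge touches a core gene.
#'
#' @param x Expression matrix (samples x genes).
#' @param core Core network as a two-column edge list (data frame or
#'   matrix of gene ids). Core genes absent from `x` are dropped with a
#'   warning.
#' @param linkage,min_cluster_size,deep_split Clustering settings (see
#'   [hierarchical_clusters()]).
#' @param c_shrink Shrinkage constant of the hub-constrained inference
#'   (default 0; 0.2 relaxes the hub restriction).
#' @param gamma,n_lambda Passed to [netard()].
#' @return Object of class `"gnce"`: `edges` (data frame with `gene_a`,
#'   `gene_b`, `weight`, `source` = core/inferred), `genes` (nodes of the
#'   extension), `assignment`, `clusters` (selected clusters), `fits`
#'   (per-cluster netard fits), `skipped` (cluster labels whose inference
#'   failed).
#' @export
extend_core_gn <- function(x, core, linkage = "complete",
                           min_cluster_size = 10, deep_split = 2,
                           c_shrink = 0, gamma = 0, n_lambda = 8) {
  core <- core_edges_df(core)
  genes <- colnames(x)
  core_genes <- unique(c(core$gene_a, core$gene_b))
  missing <- setdiff(core_genes, genes)
  if (length(missing) > 0) {
    warning("core gene(s) absent from expression data dropped: ",
            paste(missing, collapse = ", "))
    core <- core[!(core$gene_a %in% missing | core$gene_b %in% missing), ,
                 drop = FALSE]
    core_genes <- setdiff(core_genes, missing)
  }
  if (length(core_genes) == 0) {
    return(structure(list(edges = data.frame(gene_a = character(0),
                                             gene_b = character(0),
                                             weight = numeric(0),
                                             source = character(0),
                                             stringsAsFactors = FALSE),
                          genes = character(0), assignment = NULL,
                          clusters = list(), fits = list(),
                          skipped = integer(0)),
                     class = "gnce"))
  }

  d <- coexpression_distance(x)
  assign <- hierarchical_clusters(d, linkage = linkage,
                                  min_cluster_size = min_cluster_size,
                                  deep_split = deep_split)
  clusters <- select_core_clusters(assign, core_genes)

  fits <- list()
  skipped <- integer(0)
  inferred <- list()
  for (cl in clusters) {
    xs <- standardize_expression(x[, cl$members, drop = FALSE])
    fit <- tryCatch(
      netard(xs, hubs = cl$core_genes, c_shrink = c_shrink, xi = 0,
             gamma = gamma, n_lambda = n_lambda),
      error = function(e) {
        warning("cluster ", cl$cluster, " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(fit)) { skipped <- c(skipped, cl$cluster); next }
    fits[[as.character(cl$cluster)]] <- fit
    ed <- coef(fit)
    if (nrow(ed) > 0) inferred[[length(inferred) + 1]] <- ed
  }

  core$weight <- NA_real_
  core$source <- "core"
  if (length(inferred) > 0) {
    inf <- do.call(rbind, inferred)
    swap <- inf$gene_a > inf$gene_b
    inf[swap, c("gene_a", "gene_b")] <- inf[swap, c("gene_b", "gene_a")]
    inf <- inf[, c("gene_a", "gene_b", "weight")]
    inf$source <- "inferred"
    key_core <- paste(core$gene_a, core$gene_b)
    inf <- inf[!(paste(inf$gene_a, inf$gene_b) %in% key_core), , drop = FALSE]
    inf <- inf[!duplicated(paste(inf$gene_a, inf$gene_b)), , drop = FALSE]
    edges <- rbind(core, inf)
  } else {
    edges <- core
  }
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 genes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 assignment = assign, clusters = clusters, fits = fits,
                 skipped = skipped),
            class = "gnce")
}

#' @export
print.gnce <- function(x, ...) {
  cat("co-expression extension:", length(x$genes), "genes,",
      nrow(x$edges), "edges (",
      sum(x$edges$source == "core"), "core +",
      sum(x$edges$source == "inferred"), "inferred ),",
      length(x$clusters), "cluster(s) analyzed,",
      length(x$skipped), "skipped\n")
  invisible(x)
}
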