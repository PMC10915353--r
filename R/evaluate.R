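## Evaluation of an estimated network against a known truth: confusion
## metrics over unordered gene pairs, exact ROC / precision-recall sweeps
## with AUROC / AUPR, sparsity level, and hub level (degree centralization).

upper_pairs <- function(m) m[upper.tri(m)]

as_adjacency <- function(g) {
  if (!is.matrix(g) || nrow(g) != ncol(g))
    stop("graphs must be square adjacency matrices")
  a <- (g != 0)
  diag(a) <- FALSE
  a | t(a)
}

check_same_nodes <- function(g_est, g_true) {
  if (nrow(g_est) != nrow(g_true))
    stop("estimated and true graphs have different node counts")
  if (!is.null(colnames(g_est)) && !is.null(colnames(g_true)) &&
      !identical(colnames(g_est), colnames(g_true)))
    stop("estimated and true graphs are on different node sets")
}

#' Recall, fall-out and precision of an estimated graph
#'
#' Over all unordered gene pairs: recall `re` = TP/(TP+FN) (fraction of true
#' edges recovered), fall-out `fa` = FP/(FP+TN) (fraction of true non-edges
#' reported as edges), precision `pr` = TP/(TP+FP) (`NA` when the estimate
#' has no edges).
#'
#' @param g_est,g_true Adjacency matrices on the same genes.
#' @return List with `re`, `fa`, `pr` (proportions in \eqn{[0, 1]}).
#' @export
confusion_at_graph <- function(g_est, g_true) {
  g_est <- as_adjacency(g_est); g_true <- as_adjacency(g_true)
  check_same_nodes(g_est, g_true)
  est <- upper_pairs(g_est); tru <- upper_pairs(g_true)
  tp <- sum(est & tru); fp <- sum(est & !tru)
  fn <- sum(!est & tru); tn <- sum(!est & !tru)
  list(re = if (tp + fn > 0) tp / (tp + fn) else 0,
       fa = if (fp + tn > 0) fp / (fp + tn) else 0,
       pr = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' ROC and precision-recall curves of a weighted adjacency
#'
#' Sweeps the edge-weight threshold through every distinct observed weight:
#' a pair is called an edge when its weight exceeds the threshold. AUROC is
#' the trapezoidal area under recall vs fall-out; AUPR uses the continuous
#' (Davis-Goadrich) interpolation between achievable points, under which a
#' completely uninformative scorer attains exactly the edge prevalence.
#'
#' @param w Weighted adjacency matrix (scores).
#' @param g_true True adjacency matrix on the same genes.
#' @param pr_interpolation `"davis-goadrich"` (default) or `"trapezoid"`.
#' @return List of class `"roc_pr"`: `auroc`, `aupr`, `roc_points`
#'   (fa, re), `pr_points` (re, pr), `prevalence`.
#' @export
roc_pr <- function(w, g_true, pr_interpolation = c("davis-goadrich",
                                                   "trapezoid")) {
  pr_interpolation <- match.arg(pr_interpolation)
  g_true <- as_adjacency(g_true)
  check_same_nodes(w, g_true)
  scores <- upper_pairs((w + t(w)) / 2)
  labels <- upper_pairs(g_true)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0) stop("true graph has no edges; PR curve undefined")

  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]; labels <- labels[ord]
  # cumulative TP/FP at each distinct score (threshold just below it)
  cum_tp <- cumsum(labels); cum_fp <- cumsum(!labels)
  last <- !duplicated(scores, fromLast = TRUE)
  tp <- c(0, cum_tp[last]); fp <- c(0, cum_fp[last])

  re <- tp / n_pos
  fa <- if (n_neg > 0) fp / n_neg else rep(0, length(fp))
  auroc <- if (n_neg > 0) sum(diff(fa) * (re[-1] + re[-length(re)]) / 2)
           else NA_real_

  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  aupr <- 0
  for (i in seq_len(length(tp) - 1)) {
    tp_a <- tp[i]; fp_a <- fp[i]; tp_b <- tp[i + 1]; fp_b <- fp[i + 1]
    d_tp <- tp_b - tp_a
    if (d_tp == 0) next
    if (pr_interpolation == "trapezoid" && i > 1) {
      aupr <- aupr + (d_tp / n_pos) * (prec[i] + prec[i + 1]) / 2
    } else {
      # precision along the segment: TP / (TP + FP_a + s (TP - TP_a)),
      # FP linear in TP with slope s
      s <- (fp_b - fp_a) / d_tp
      cc <- fp_a - s * tp_a
      if (abs(cc) < 1e-12) {
        aupr <- aupr + (d_tp / n_pos) / (1 + s)
      } else {
        f <- function(t) t / (1 + s) -
          cc / (1 + s)^2 * log((1 + s) * t + cc)
        aupr <- aupr + (f(tp_b) - f(tp_a)) / n_pos
      }
    }
  }

  structure(list(auroc = auroc, aupr = aupr,
                 roc_points = cbind(fa = fa, re = re),
                 pr_points = cbind(re = re, pr = prec),
                 prevalence = n_pos / (n_pos + n_neg)),
            class = "roc_pr")
}

#' @export
print.roc_pr <- function(x, ...) {
  cat("AUROC =", format(x$auroc, digits = 4),
      "| AUPR =", format(x$aupr, digits = 4),
      "| prevalence =", format(x$prevalence, digits = 4), "\n")
  invisible(x)
}

#' Sparsity level of a graph
#'
#' Fraction of missing edges among all unordered gene pairs:
#' \eqn{1 - |E| / \binom{p}{2}}.
#'
#' @param g Adjacency matrix.
#' @return Scalar in \eqn{[0, 1]}.
#' @export
sparsity_level <- function(g) {
  g <- as_adjacency(g)
  p <- nrow(g)
  if (p < 2) stop("need at least 2 nodes")
  1 - sum(upper_pairs(g)) / (p * (p - 1) / 2)
}

#' Hub level (degree centralization) of a graph
#'
#' Freeman degree centralization,
#' \eqn{\sum_i (d_{\max} - d_i) / ((p-1)(p-2))}: 0 for a regular graph, 1 for
#' a star.
#'
#' @param g Adjacency matrix.
#' @return Scalar in \eqn{[0, 1]}.
#' @export
hub_level <- function(g) {
  g <- as_adjacency(g)
  p <- nrow(g)
  if (p < 3) stop("hub level needs at least 3 nodes")
  d <- colSums(g)
  sum(max(d) - d) / ((p - 1) * (p - 2))
}

#' Evaluate an estimated network against the truth
#'
#' Bundles the confusion metrics of the thresholded graph, AUROC/AUPR of the
#' weights, and the estimated graph's sparsity and hub levels.
#'
#' @param w Estimated weighted adjacency matrix.
#' @param g_true True adjacency matrix.
#' @return List with `re`, `fa`, `pr`, `auroc`, `aupr`, `sl`, `hl`.
#' @export
evaluate_weights <- function(w, g_true) {
  conf <- confusion_at_graph(w > 0, g_true)
  curves <- roc_pr(w, g_true)
  c(conf, list(auroc = curves$auroc, aupr = curves$aupr,
               sl = sparsity_level(w > 0), hl = hub_level(w > 0)))
}
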