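## Expression-matrix utilities. An expression matrix is a plain numeric
## matrix, samples in rows, genes in columns, gene identifiers as colnames.

#' Standardize an expression matrix
#'
#' Centers each gene (column) to mean 0 and scales it to standard deviation 1
#' (denominator N - 1), the conventional preprocessing before partial
#' correlation network inference on (log-transformed) expression data.
#'
#' @param x Numeric matrix, samples x genes.
#' @return The standardized matrix, with attribute `standardized = TRUE`.
#' @export
standardize_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix (samples x genes)")
  if (nrow(x) < 2)
    stop("need at least 2 samples to standardize")
  if (any(is.na(x)))
    stop("'x' contains missing values")
  s <- apply(x, 2, sd)
  if (any(s == 0)) {
    bad <- colnames(x)[s == 0]
    if (is.null(bad)) bad <- which(s == 0)
    stop("constant column(s): ", paste(bad, collapse = ", "))
  }
  out <- scale(x, center = TRUE, scale = s)
  out <- out[, , drop = FALSE]
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "standardized") <- TRUE
  out
}

is_standardized <- function(x, tol = 1e-6) {
  isTRUE(attr(x, "standardized")) ||
    (max(abs(colMeans(x))) < tol && max(abs(apply(x, 2, sd) - 1)) < tol)
}

ensure_standardized <- function(x) {
  if (is_standardized(x)) x else standardize_expression(x)
}
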