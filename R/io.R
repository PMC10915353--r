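## Delimited-text I/O: expression matrices (TSV/CSV, samples x genes), edge
## lists, hub lists. Writers order rows deterministically so outputs diff.

detect_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read an expression matrix from delimited text
#'
#' Expects a header row of gene identifiers and a first column of sample
#' identifiers (samples x genes); use `transpose = TRUE` for genes x samples
#' files.
#'
#' @param path File path (TSV by default, CSV if the extension is .csv).
#' @param transpose Set to TRUE when rows are genes.
#' @param sep Field separator; inferred from the extension when NULL.
#' @return Numeric matrix, samples x genes.
#' @export
read_expression_matrix <- function(path, transpose = FALSE, sep = NULL) {
  sep <- sep %||% detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric values in ", path)
  if (transpose) m <- t(m)
  if (anyDuplicated(colnames(m)))
    stop("duplicated gene identifier(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (any(is.na(m))) {
    idx <- which(is.na(m), arr.ind = TRUE)
    stop("missing values, first at row ", rownames(m)[idx[1, 1]] %||% idx[1, 1],
         ", column ", colnames(m)[idx[1, 2]] %||% idx[1, 2])
  }
  m
}

#' Write an expression matrix
#'
#' @param x Numeric matrix, samples x genes.
#' @param path Destination (TSV unless the extension is .csv).
#' @param sep Field separator; inferred when NULL.
#' @export
write_expression_matrix <- function(x, path, sep = NULL) {
  sep <- sep %||% detect_sep(path)
  df <- data.frame(sample = rownames(x) %||% paste0("s", seq_len(nrow(x))),
                   x, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an undirected edge list
#'
#' Two mandatory columns (gene_a, gene_b) and an optional weight column;
#' lines starting with '#' are comments. Duplicate and reversed-duplicate
#' edges are collapsed (first weight kept) and self-loops dropped with a
#' warning.
#'
#' @param path File path.
#' @param sep Field separator; inferred when NULL.
#' @return Data frame with `gene_a`, `gene_b` and, when present, `weight`,
#'   sorted canonically.
#' @export
read_edge_list <- function(path, sep = NULL) {
  sep <- sep %||% detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list needs at least two columns: ", path)
  e <- data.frame(gene_a = as.character(df[[1]]),
                  gene_b = as.character(df[[2]]),
                  stringsAsFactors = FALSE)
  if (ncol(df) >= 3 && is.numeric(df[[3]])) e$weight <- df[[3]]
  loops <- e$gene_a == e$gene_b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    e <- e[!loops, , drop = FALSE]
  }
  swap <- e$gene_a > e$gene_b
  if ("weight" %in% names(e)) {
    e[swap, c("gene_a", "gene_b")] <- e[swap, c("gene_b", "gene_a")]
  } else {
    e[swap, c("gene_a", "gene_b")] <- e[swap, c("gene_b", "gene_a")]
  }
  e <- e[!duplicated(paste(e$gene_a, e$gene_b)), , drop = FALSE]
  e <- e[order(e$gene_a, e$gene_b), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Write an undirected edge list
#'
#' Accepts either an edge data frame (`gene_a`, `gene_b`, optional further
#' columns) or a weighted/logical adjacency matrix with gene dimnames.
#'
#' @param edges Edge data frame or adjacency matrix.
#' @param path Destination.
#' @param sep Field separator; inferred when NULL.
#' @export
write_edge_list <- function(edges, path, sep = NULL) {
  sep <- sep %||% detect_sep(path)
  if (is.matrix(edges) && nrow(edges) == ncol(edges) &&
      !is.character(edges)) {
    edges <- adjacency_to_edges(edges)
  }
  stopifnot(is.data.frame(edges))
  ord <- order(edges$gene_a, edges$gene_b)
  write.table(edges[ord, , drop = FALSE], path, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a hub gene list (one identifier per line)
#'
#' @param path File path; blank lines and '#' comments are skipped.
#' @return Character vector of gene ids.
#' @export
read_hub_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Convert an adjacency (or weight) matrix to an edge data frame
#'
#' @param adj Square matrix with gene dimnames; nonzero entries are edges.
#' @return Data frame with `gene_a`, `gene_b`, `weight`.
#' @export
adjacency_to_edges <- function(adj) {
  genes <- colnames(adj) %||% paste0("g", seq_len(ncol(adj)))
  idx <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  e <- data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
                  weight = as.numeric(adj[idx]), stringsAsFactors = FALSE)
  e[order(e$gene_a, e$gene_b), , drop = FALSE]
}

#' Convert an edge data frame to an adjacency matrix
#'
#' @param edges Data frame with gene pair columns and optional `weight`.
#' @param genes Node set (defaults to the genes present in `edges`).
#' @return Numeric p x p symmetric matrix (weights, or 1 for unweighted).
#' @export
edges_to_adjacency <- function(edges, genes = NULL) {
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  genes <- genes %||% sort(unique(c(a, b)))
  unknown <- setdiff(c(a, b), genes)
  if (length(unknown) > 0)
    stop("edge references unknown gene(s): ",
         paste(unique(unknown), collapse = ", "))
  w <- if ("weight" %in% names(edges)) edges$weight else rep(1, length(a))
  adj <- matrix(0, length(genes), length(genes),
                dimnames = list(genes, genes))
  adj[cbind(a, b)] <- w
  adj[cbind(b, a)] <- w
  adj
}
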