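#' Hierarchical clustering of an expression matrix
#'
#' Ward-linkage agglomerative clustering with correlation distance
#' (`1 - Pearson r`), the standard recipe for co-clustering tissue expression
#' profiles of ligands and candidate receptors. Rows with zero variance have
#' no defined correlation; they are assigned the maximal correlation distance
#' (2) with a warning. `axis = "both"` clusters genes and tissues.
#'
#' @param expr numeric matrix, genes x tissues, nonnegative, with unique row
#'   and column names.
#' @param axis `"genes"`, `"tissues"`, or `"both"`.
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @param linkage passed to [stats::hclust] (default `"ward.D2"`).
#' @return List with `genes` and/or `tissues`: each an [stats::hclust] tree
#'   plus the leaf `order` (labels).
#' @export
hierarchical_cluster <- function(expr, axis = c("genes", "tissues", "both"),
                                 metric = c("correlation", "euclidean"),
                                 linkage = "ward.D2") {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("expression values must be nonnegative")
  if (is.null(rownames(expr)) || is.null(colnames(expr)) ||
      anyDuplicated(rownames(expr)) || anyDuplicated(colnames(expr)))
    stop("expression matrix needs unique row and column names")
  out <- list()
  if (axis %in% c("genes", "both")) out$genes <- cluster_axis(expr, metric, linkage)
  if (axis %in% c("tissues", "both")) out$tissues <- cluster_axis(t(expr), metric, linkage)
  out
}

cluster_axis <- function(m, metric, linkage) {
  if (nrow(m) < 2) stop("need >= 2 items on the clustered axis")
  d <- if (metric == "correlation") correlation_dist(m) else stats::dist(m)
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, order = rownames(m)[hc$order])
}

correlation_dist <- function(m) {
  r <- suppressWarnings(stats::cor(t(m)))
  if (anyNA(r)) {
    warning("constant rows have undefined correlation; assigned maximal distance")
    r[is.na(r)] <- -1
    diag(r) <- 1
  }
  stats::as.dist(1 - r)
}

#' Pairwise expression correlation matrix
#'
#' Pearson correlation of gene expression profiles across tissues (the
#' multivariate-correlation heatmap underlying co-expression arguments for an
#' interaction): symmetric, unit diagonal.
#'
#' @param expr genes x tissues numeric matrix.
#' @param genes optional subset of row names.
#' @return Symmetric correlation matrix over the selected genes.
#' @export
correlation_heatmap <- function(expr, genes = NULL) {
  expr <- as.matrix(expr)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(expr))
    if (length(missing))
      stop("genes not in matrix: ", paste(missing, collapse = ", "))
    expr <- expr[genes, , drop = FALSE]
  }
  stats::cor(t(expr))
}

#' Read / write expression matrices as TSV
#'
#' Rows are genes, columns tissues; first column holds gene names.
#'
#' @param path TSV path.
#' @return Numeric matrix with dimnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' @rdname read_expression
#' @param expr genes x tissues matrix.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), as.data.frame(expr, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
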