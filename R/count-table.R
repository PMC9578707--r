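#' Guide-by-sample count table
#'
#' Container for sgRNA read counts: a nonnegative integer matrix (guides x
#' samples), guide metadata (gene, category), and per-sample selection-round
#' metadata.
#'
#' @param counts integer matrix, rownames = guide ids, colnames = sample ids.
#' @param library data.frame with columns `guide_id`, `gene_id`, `category`
#'   covering every row of `counts`.
#' @param samples data.frame with columns `sample_id`, `round`; defaults to
#'   rounds parsed from sample names of the form `R<k>`.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, library, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have guide rownames and sample colnames")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts != round(counts))) stop("counts must be integers")
  library <- as.data.frame(library, stringsAsFactors = FALSE)
  req <- c("guide_id", "gene_id", "category")
  if (!all(req %in% names(library)))
    stop("library must have columns guide_id, gene_id, category")
  if (anyDuplicated(library$guide_id))
    stop("duplicate guide_id in library: ",
         library$guide_id[anyDuplicated(library$guide_id)])
  bad <- setdiff(library$category, c("gene", "safe", "nontargeting"))
  if (length(bad)) stop("unknown guide category: ", paste(bad, collapse = ", "))
  missing <- setdiff(rownames(counts), library$guide_id)
  if (length(missing))
    stop("guides in counts missing from library: ",
         paste(utils::head(missing, 5), collapse = ", "))
  library <- library[match(rownames(counts), library$guide_id), , drop = FALSE]
  rownames(library) <- NULL
  if (is.null(samples)) {
    rounds <- suppressWarnings(as.integer(sub("^R", "", colnames(counts))))
    samples <- data.frame(sample_id = colnames(counts), round = rounds)
  }
  if (!all(colnames(counts) %in% samples$sample_id))
    stop("every sample needs round metadata")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, library = library, samples = samples),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("Guide count table: %d guides (%d gene-targeting, %d control) x %d samples\n",
              nrow(x$counts), sum(x$library$category == "gene"),
              sum(x$library$category != "gene"), ncol(x$counts)))
  cat("  samples:", paste(sprintf("%s (round %s)", x$samples$sample_id,
                                  x$samples$round), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write count tables as TSV
#'
#' The on-disk format has columns `guide_id`, `gene_id`, `category`, then one
#' column of integer counts per sample. Rounds are parsed from sample names of
#' the form `R<k>` unless supplied.
#'
#' @param path file path.
#' @param rounds optional integer vector of rounds, one per sample column.
#' @return A [count_table].
#' @export
read_count_table <- function(path, rounds = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("guide_id", "gene_id", "category")
  if (!all(meta %in% names(df))) stop("missing required columns in ", path)
  sample_cols <- setdiff(names(df), meta)
  if (!length(sample_cols)) stop("no sample columns in ", path)
  counts <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(counts) <- df$guide_id
  samples <- NULL
  if (!is.null(rounds))
    samples <- data.frame(sample_id = sample_cols, round = rounds)
  count_table(counts, df[, meta], samples = samples)
}

#' @rdname read_count_table
#' @param ct a [count_table].
#' @export
write_count_table <- function(ct, path) {
  stopifnot(inherits(ct, "count_table"))
  out <- cbind(ct$library, as.data.frame(ct$counts, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize counts to per-sample frequencies
#'
#' Adds a pseudocount to every count (so dropout guides keep a finite
#' log-frequency) and divides by the column total; each column then sums to 1.
#'
#' @param x a [count_table] or count matrix.
#' @param pseudocount added to every count before normalization (default 0.5).
#' @return Matrix of frequencies with the dimensions of the input counts.
#' @export
normalize_counts <- function(x, pseudocount = 0.5) {
  counts <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  adj <- counts + pseudocount
  sweep(adj, 2, colSums(adj), "/")
}

#' Per-guide log2 enrichment between two samples
#'
#' For each guide, `x = log2(freq_selected / freq_reference)` after
#' pseudocount normalization. Each selection round is conventionally compared
#' to the naive (round 0) library.
#'
#' @param ct a [count_table].
#' @param selected,reference sample ids present in `ct`.
#' @inheritParams normalize_counts
#' @return data.frame with columns `guide_id`, `gene_id`, `category`, `x`.
#' @export
guide_log_enrichment <- function(ct, selected, reference, pseudocount = 0.5) {
  stopifnot(inherits(ct, "count_table"))
  for (s in c(selected, reference))
    if (!s %in% colnames(ct$counts)) stop("no such sample: ", s)
  freq <- normalize_counts(ct, pseudocount)
  data.frame(ct$library,
             x = log2(freq[, selected] / freq[, reference]),
             row.names = NULL, stringsAsFactors = FALSE)
}
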