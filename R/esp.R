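#' Combined ESP ranking score
#'
#' The screen's combined ranking statistic for a gene:
#' `esp = (effect + score) / p`, with the p-value floored at
#' `p_floor = 1/(n_perm + 1)` (the smallest attainable permutation p) so the
#' ratio is always defined.
#'
#' @param effect casTLE-style effect (log2 units).
#' @param score casTLE-style confidence score.
#' @param p_value permutation p-value in `(0, 1]` (0 is clamped to the floor).
#' @param p_floor smallest usable p (default `1/10001`, i.e. 10,000
#'   permutations).
#' @return Numeric ESP score(s); all arguments vectorized.
#' @examples
#' esp_score(4, 10, 0.01)  # 1400
#' @export
esp_score <- function(effect, score, p_value, p_floor = 1 / 10001) {
  if (any(p_value < 0 | p_value > 1)) stop("p_value must lie in [0, 1]")
  (effect + score) / pmax(p_value, p_floor)
}

#' First-pass hit filter
#'
#' Retains genes passing all of: effect > 2, score > 2, p < 0.05 (strict
#' inequalities, the printed cut-offs), annotated inside the membrane or
#' secreted proteome, and not on the false-positive blacklist.
#'
#' @param results a `gene_results` data.frame (columns `gene`, `effect`,
#'   `score`, `p_value`).
#' @param annotation named character vector or data.frame (`gene_id`,
#'   `class`) assigning each gene one of `"TM1-membrane"`, `"TM2+-membrane"`,
#'   `"secreted"`, `"other"`; genes missing from it are classed `"other"`.
#' @param blacklist character vector of known contaminant genes (default
#'   empty; the slot exists because recurrent screen contaminants are usually
#'   curated per platform).
#' @param effect_cut,score_cut,p_cut the cut-offs (defaults 2, 2, 0.05).
#' @return The retained rows, with an `annotation_class` column added.
#' @export
first_pass_filter <- function(results, annotation = NULL,
                              blacklist = character(),
                              effect_cut = 2, score_cut = 2, p_cut = 0.05) {
  cls <- annotation_classes(results$gene, annotation)
  keep <- results$effect > effect_cut & results$score > score_cut &
    results$p_value < p_cut &
    cls %in% c("TM1-membrane", "TM2+-membrane", "secreted") &
    !(results$gene %in% blacklist)
  out <- results[keep, , drop = FALSE]
  out$annotation_class <- cls[keep]
  out
}

annotation_classes <- function(genes, annotation) {
  valid <- c("TM1-membrane", "TM2+-membrane", "secreted", "other")
  if (is.null(annotation)) return(rep("other", length(genes)))
  if (is.data.frame(annotation))
    annotation <- stats::setNames(annotation$class, annotation$gene_id)
  cls <- unname(annotation[genes])
  cls[is.na(cls)] <- "other"
  bad <- setdiff(unique(cls), valid)
  if (length(bad)) stop("unknown annotation class: ", paste(bad, collapse = ", "))
  cls
}

#' Classify an ESP enrichment trajectory
#'
#' A gene's ESP scores over consecutive selection rounds are classed
#' `positive` when the series is nondecreasing up to a relative tolerance
#' (each step may dip by at most `tau` of the previous value) and the final
#' round exceeds the first; `negative` when the final round is below the
#' first; `flat` otherwise. Genuinely enriching receptors show positive
#' trajectories, while false positives often spike once and fall back.
#'
#' @param esp numeric vector of per-round ESP scores (>= 2 rounds).
#' @param tau relative dip tolerated per step (default 0.1).
#' @return One of `"positive"`, `"negative"`, `"flat"`.
#' @export
classify_trajectory <- function(esp, tau = 0.1) {
  esp <- as.numeric(esp)
  if (length(esp) < 2)
    stop("trajectory needs >= 2 rounds; with a single round use rank_hits() only")
  prev <- esp[-length(esp)]
  nondecr <- all(diff(esp) >= -tau * abs(prev))
  if (nondecr && esp[length(esp)] > esp[1]) return("positive")
  if (esp[length(esp)] < esp[1]) return("negative")
  "flat"
}

#' Rank genes by ESP score
#'
#' Descending ESP; ties broken by higher score, then lexicographic gene id.
#'
#' @param results data.frame with columns `gene`, `score` and `esp`.
#' @return The same rows sorted, with a `rank` column.
#' @export
rank_hits <- function(results) {
  ord <- order(-results$esp, -results$score, results$gene)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Call hits from per-round gene results
#'
#' Applies the first-pass filter to the final round, computes ESP
#' trajectories over all rounds, and calls as hits only the filtered genes
#' with a positive trajectory. All genes are returned (ranked by final-round
#' ESP) with their filter and trajectory flags, so near-misses remain
#' inspectable.
#'
#' @param rounds list of `gene_results`, one per selection round, in round
#'   order (>= 2 rounds for trajectory classification).
#' @inheritParams first_pass_filter
#' @param tau trajectory dip tolerance (see [classify_trajectory()]).
#' @param p_floor ESP p-value floor; defaults to `1/(n_perm + 1)` of the
#'   final round.
#' @return data.frame of class `hit_records`: per-round ESP columns,
#'   final-round metrics, `annotation_class`, `trajectory`,
#'   `passes_first_pass`, `called`, `rank`.
#' @export
call_hits <- function(rounds, annotation = NULL, blacklist = character(),
                      effect_cut = 2, score_cut = 2, p_cut = 0.05,
                      tau = 0.1, p_floor = NULL) {
  if (inherits(rounds, "gene_results")) rounds <- list(rounds)
  if (!length(rounds) || !nrow(rounds[[1]])) {
    out <- data.frame(gene = character(), trajectory = character(),
                      passes_first_pass = logical(), called = logical(),
                      rank = integer())
    class(out) <- c("hit_records", "data.frame")
    return(out)
  }
  if (length(rounds) < 2)
    stop("trajectory-based calling needs >= 2 rounds; with a single round ",
         "use first_pass_filter() + rank_hits()")
  if (is.null(p_floor)) {
    np <- attr(rounds[[length(rounds)]], "n_perm")
    p_floor <- if (is.null(np)) 1 / 10001 else 1 / (np + 1)
  }
  genes <- rounds[[1]]$gene
  esp <- sapply(rounds, function(r) {
    esp_score(r$effect, r$score, r$p_value, p_floor)[match(genes, r$gene)]
  })
  esp <- matrix(esp, nrow = length(genes))
  colnames(esp) <- paste0("esp_R", seq_along(rounds))

  final <- rounds[[length(rounds)]]
  final <- final[match(genes, final$gene), , drop = FALSE]
  cls <- annotation_classes(genes, annotation)
  passes <- genes %in% first_pass_filter(final, annotation, blacklist,
                                         effect_cut, score_cut, p_cut)$gene
  trajectory <- apply(esp, 1, classify_trajectory, tau = tau)

  out <- data.frame(gene = genes, as.data.frame(esp),
                    effect = final$effect, score = final$score,
                    p_value = final$p_value,
                    esp = esp[, ncol(esp)],
                    annotation_class = cls, trajectory = trajectory,
                    passes_first_pass = passes,
                    called = passes & trajectory == "positive",
                    stringsAsFactors = FALSE)
  out <- rank_hits(out)
  class(out) <- c("hit_records", "data.frame")
  out
}

#' @export
print.hit_records <- function(x, n = 10, ...) {
  cat(sprintf("Hit records: %d genes, %d pass first-pass filter, %d called\n",
              nrow(x), sum(x$passes_first_pass), sum(x$called)))
  cols <- intersect(c("rank", "gene", "effect", "score", "p_value", "esp",
                      "trajectory", "called"), names(x))
  print.data.frame(utils::head(x[, cols], n), row.names = FALSE, digits = 4)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more genes\n")
  invisible(x)
}

#' Write hit records as TSV
#'
#' @param hits a `hit_records` data.frame.
#' @param path output file.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
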