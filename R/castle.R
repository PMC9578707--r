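#' Effect-size search grid
#'
#' Uniform grid of candidate maximum effect sizes (log2 units) containing 0,
#' spanning negative and positive effects.
#'
#' @param lo,hi grid bounds (default -15, 15 log2 units).
#' @param step grid step (default 0.1).
#' @return Numeric vector (exactly representable multiples of `step`).
#' @export
effect_grid <- function(lo = -15, hi = 15, step = 0.1) {
  g <- seq(round(lo / step), round(hi / step)) * step
  if (!any(g == 0)) stop("effect grid must contain 0")
  if (min(g) >= 0 || max(g) <= 0)
    stop("effect grid must span negative and positive effects")
  g
}

# Per-guide log-density matrix: rows = guide enrichments, cols = grid effects.
# Under effect theta, a guide's true shift is uniform on [0, theta] (variable
# guide efficacy), so f(x|theta) = (1/|theta|) Int_0^|theta| f0(x - sgn(theta) t) dt,
# evaluated by fixed-grid trapezoid quadrature; theta = 0 is exactly f0.
guide_logdens_matrix <- function(stats, null, grid, n_trapz = 64) {
  n <- length(stats)
  L <- matrix(null$floor, n, length(grid))
  w <- c(0.5, rep(1, n_trapz - 2), 0.5)
  w <- w / sum(w)                      # trapezoid weights, normalized by |theta|
  fl <- exp(null$floor)
  for (j in seq_along(grid)) {
    th <- grid[j]
    if (th == 0) {
      L[, j] <- pmax(log(null_density(null, stats)), null$floor)
    } else {
      tt <- seq(0, abs(th), length.out = n_trapz) * sign(th)
      q <- rep(stats, times = n_trapz) - rep(tt, each = n)
      f <- matrix(null_density(null, q), n, n_trapz) %*% w
      L[, j] <- pmax(log(pmax(f, fl)), null$floor)
    }
  }
  L
}

#' Gene log-likelihood under a candidate maximum effect
#'
#' For effect `theta = 0` this is the null log-likelihood
#' `sum(log f0(x_i))`. For `theta != 0` each guide's density is a uniform
#' mixture of shifted nulls,
#' `f(x|theta) = (1/|theta|) * integral_0^{|theta|} f0(x - sign(theta) t) dt`,
#' modeling guides whose realized effect lies anywhere between 0 (inactive
#' guide) and the gene's maximum effect `theta`.
#'
#' @param stats numeric vector of the gene's guide log2 enrichments.
#' @param null a [fit_null()] model.
#' @param theta candidate maximum effect (log2 units).
#' @param n_trapz trapezoid quadrature points (default 64).
#' @return The summed per-guide log density.
#' @export
gene_log_likelihood <- function(stats, null, theta, n_trapz = 64) {
  stopifnot(inherits(null, "null_model"))
  if (!length(stats)) stop("no guide statistics supplied")
  sum(guide_logdens_matrix(stats, null, theta, n_trapz))
}

# Row-wise maximum of a matrix without extra dependencies.
rowmax_ <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmax(out, m[, j])
  out
}

# Pick the argmax effect with a deterministic tie-break: smallest |theta|,
# positive before negative at equal magnitude.
argmax_effect <- function(L_row, grid, tol = 1e-9) {
  ord <- order(abs(grid), -grid)
  cand <- ord[L_row[ord] >= max(L_row) - tol]
  grid[cand[1]]
}

#' Estimate a gene's maximum effect and confidence score
#'
#' Grid search of [gene_log_likelihood()] over candidate effects. The effect
#' estimate is the grid argmax; the score is the likelihood-ratio statistic
#' `2 * (L(effect) - L(0))` clipped at 0; the effect interval is the profile
#' set `{theta : L(theta) >= L(effect) - 2}` (~95%), reported via its bounds.
#'
#' @inheritParams gene_log_likelihood
#' @param grid candidate effects from [effect_grid()].
#' @return List with `effect`, `score`, `effect_min`, `effect_max`.
#' @export
estimate_gene_effect <- function(stats, null, grid = effect_grid(),
                                 n_trapz = 64) {
  if (min(grid) >= 0 || max(grid) <= 0 || !any(grid == 0))
    stop("grid must contain 0 and span negative and positive effects")
  L <- colSums(guide_logdens_matrix(stats, null, grid, n_trapz))
  effect <- argmax_effect(L, grid)
  Lmax <- max(L)
  score <- max(0, 2 * (Lmax - L[grid == 0]))
  keep <- grid[L >= Lmax - 2]
  list(effect = effect, score = score,
       effect_min = min(keep), effect_max = max(keep))
}

# Permuted pseudo-gene scores: draw n_perm pseudo-genes of n_guides statistics
# (rows of the precomputed log-density matrix) with replacement and recompute
# the score for each. Chunked to bound memory.
perm_scores_from_matrix <- function(L, n_guides, n_perm, i0) {
  out <- numeric(n_perm)
  chunk <- max(1L, floor(250000 / n_guides))
  done <- 0L
  while (done < n_perm) {
    k <- min(chunk, n_perm - done)
    idx <- sample.int(nrow(L), k * n_guides, replace = TRUE)
    S <- rowsum(L[idx, , drop = FALSE], group = rep(seq_len(k), each = n_guides))
    out[done + seq_len(k)] <- pmax(0, 2 * (rowmax_(S) - S[, i0]))
    done <- done + k
  }
  out
}

#' Permutation p-value for an observed gene score
#'
#' Draws `n_perm` pseudo-genes of `n_guides` enrichments sampled with
#' replacement from the pool of all gene-targeting guide enrichments,
#' recomputes the score for each, and returns
#' `p = (1 + #\{permuted >= observed\}) / (n_perm + 1)`, so p is bounded below
#' by `1/(n_perm + 1)`.
#'
#' @param observed_score the gene's score.
#' @param n_guides number of guides in the gene.
#' @param pool numeric vector of all gene-targeting guide enrichments.
#' @inheritParams estimate_gene_effect
#' @param n_perm number of permutations (default 10000).
#' @return Permutation p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(observed_score, n_guides, pool, null,
                               n_perm = 10000, grid = effect_grid(),
                               n_trapz = 64) {
  if (length(pool) < n_guides) stop("pool smaller than n_guides")
  if (n_perm < 1) stop("n_perm must be >= 1")
  L <- guide_logdens_matrix(pool, null, grid, n_trapz)
  perm <- perm_scores_from_matrix(L, n_guides, n_perm, which(grid == 0))
  (1 + sum(perm >= observed_score)) / (n_perm + 1)
}

#' Default analysis configuration
#'
#' @param pseudocount normalization pseudocount (default 0.5).
#' @param grid effect search grid (default [effect_grid()]).
#' @param n_perm permutations for p-values (default 10000).
#' @param n_trapz quadrature points for the efficacy mixture (default 64).
#' @param seed RNG seed for the permutation draw.
#' @return List of configuration values.
#' @export
analysis_config <- function(pseudocount = 0.5, grid = effect_grid(),
                            n_perm = 10000, n_trapz = 64, seed = 1L) {
  list(pseudocount = pseudocount, grid = grid, n_perm = n_perm,
       n_trapz = n_trapz, seed = seed)
}

#' Gene-level analysis of one selection round
#'
#' Composes the full gene-level inference for one selected sample against a
#' reference (conventionally the naive round-0 library): per-guide log2
#' enrichment, empirical null from the control guides, per-gene
#' maximum-likelihood effect and score, and permutation p-values using the
#' pool of all gene-targeting guide enrichments. Permutation score
#' distributions are shared across genes with the same guide count, which
#' leaves p-values unchanged while making `n_perm = 10000` cheap.
#'
#' @param ct a [count_table].
#' @param selected,reference sample ids in `ct`.
#' @param config an [analysis_config()].
#' @return A data.frame of class `gene_results` with columns `gene`,
#'   `n_guides`, `effect`, `score`, `p_value`, `effect_min`, `effect_max`.
#' @export
analyze_round <- function(ct, selected, reference, config = analysis_config()) {
  enr <- guide_log_enrichment(ct, selected, reference, config$pseudocount)
  is_ctrl <- enr$category %in% c("safe", "nontargeting")
  if (sum(is_ctrl) < 20)
    stop("need at least 20 control guides to fit the empirical null")
  null <- fit_null(enr$x[is_ctrl])
  gene_rows <- enr[enr$category == "gene", , drop = FALSE]
  genes <- unique(gene_rows$gene_id)
  grid <- config$grid
  i0 <- which(grid == 0)

  L <- guide_logdens_matrix(gene_rows$x, null, grid, config$n_trapz)
  Lg <- rowsum(L, group = gene_rows$gene_id)          # gene x grid log-lik
  Lg <- Lg[genes, , drop = FALSE]
  n_guides <- as.integer(table(gene_rows$gene_id)[genes])

  Lmax <- rowmax_(Lg)
  score <- pmax(0, 2 * (Lmax - Lg[, i0]))
  effect <- numeric(length(genes))
  effect_min <- numeric(length(genes))
  effect_max <- numeric(length(genes))
  for (i in seq_along(genes)) {
    effect[i] <- argmax_effect(Lg[i, ], grid)
    keep <- grid[Lg[i, ] >= Lmax[i] - 2]
    effect_min[i] <- min(keep)
    effect_max[i] <- max(keep)
  }

  if (!is.null(config$seed)) set.seed(config$seed)
  p_value <- numeric(length(genes))
  for (n in unique(n_guides)) {
    perm <- perm_scores_from_matrix(L, n, config$n_perm, i0)
    for (i in which(n_guides == n))
      p_value[i] <- (1 + sum(perm >= score[i])) / (config$n_perm + 1)
  }

  res <- data.frame(gene = genes, n_guides = n_guides, effect = effect,
                    score = score, p_value = p_value,
                    effect_min = effect_min, effect_max = effect_max,
                    stringsAsFactors = FALSE)
  attr(res, "selected") <- selected
  attr(res, "reference") <- reference
  attr(res, "n_perm") <- config$n_perm
  class(res) <- c("gene_results", "data.frame")
  res
}

#' @export
print.gene_results <- function(x, n = 10, ...) {
  cat(sprintf("Gene-level screen results: %s vs %s (%d genes, %d permutations)\n",
              attr(x, "selected"), attr(x, "reference"), nrow(x),
              attr(x, "n_perm")))
  ord <- order(-x$score)
  print.data.frame(utils::head(x[ord, ], n), row.names = FALSE, digits = 4)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more genes\n")
  invisible(x)
}

#' Write gene results as TSV
#'
#' @param results a `gene_results` data.frame (or a list of them, one per
#'   round, written with a `round` column).
#' @param path output file.
#' @export
write_gene_results <- function(results, path) {
  if (inherits(results, "gene_results")) results <- list(results)
  out <- do.call(rbind, lapply(results, function(r) {
    r$round <- attr(r, "selected")
    as.data.frame(r)
  }))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
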