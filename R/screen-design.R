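#' Describe a pooled CRISPRa screening library
#'
#' A screen design records the target genes, the number of sgRNAs per target,
#' the number of matched control guides (split between safe-targeting and
#' non-targeting classes), and the ground-truth binding strength of any true
#' receptors present. Binding strength scales the bead-capture probability of
#' cells whose guide activates that receptor; `0` means the gene does not bind
#' the bait, `1` means saturating capture for a fully activated cell.
#'
#' @param gene_ids character vector of unique target gene identifiers.
#' @param guides_per_gene sgRNAs designed per target (default 10, the library
#'   design used throughout).
#' @param n_controls number of control guides matched to the library.
#' @param true_receptors named numeric vector mapping gene ids to binding
#'   strengths in `[0, 1]`. Genes absent from this vector have strength 0.
#' @param library_label one of `"TM1"`, `"TM2+"`, `"mini"`.
#' @return An object of class `screen_design`.
#' @examples
#' d <- screen_design(paste0("G", 1:10), n_controls = 100,
#'                    true_receptors = c(G1 = 1), library_label = "mini")
#' d
#' @export
screen_design <- function(gene_ids, guides_per_gene = 10, n_controls = 0,
                          true_receptors = numeric(), library_label = "mini") {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) < 1L) stop("at least one target gene is required")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (guides_per_gene < 1L) stop("guides_per_gene must be >= 1")
  if (n_controls < 0L) stop("n_controls must be >= 0")
  true_receptors <- unlist(true_receptors)
  if (length(true_receptors)) {
    if (is.null(names(true_receptors)) || any(!nzchar(names(true_receptors))))
      stop("true_receptors must be a named vector")
    unknown <- setdiff(names(true_receptors), gene_ids)
    if (length(unknown))
      stop("true_receptors refers to genes not in the design: ",
           paste(unknown, collapse = ", "))
    if (any(true_receptors < 0 | true_receptors > 1))
      stop("binding strengths must lie in [0, 1]")
  }
  library_label <- match.arg(library_label, c("TM1", "TM2+", "mini"))
  structure(
    list(gene_ids = gene_ids,
         guides_per_gene = as.integer(guides_per_gene),
         n_controls = as.integer(n_controls),
         true_receptors = true_receptors,
         library_label = library_label),
    class = "screen_design")
}

#' @export
print.screen_design <- function(x, ...) {
  cat(sprintf("CRISPRa screen design [%s]\n", x$library_label))
  cat(sprintf("  %d targets x %d sgRNAs = %d gene-targeting guides; %d controls\n",
              length(x$gene_ids), x$guides_per_gene,
              length(x$gene_ids) * x$guides_per_gene, x$n_controls))
  if (length(x$true_receptors))
    cat(sprintf("  true receptors: %s\n",
                paste(sprintf("%s (%.2g)", names(x$true_receptors),
                              x$true_receptors), collapse = ", ")))
  invisible(x)
}

#' Simulation parameters for a bead-selection screen
#'
#' Parameters of the generative model: library complexity, number of
#' consecutive MACS selection rounds, per-cell background and maximal bead
#' capture probabilities, the dispersion of per-guide CRISPRa activation
#' efficacy, sequencing depth per sample, and the spread of initial guide
#' abundance.
#'
#' Per-guide activation efficacy is drawn from a Beta distribution with mean
#' `efficacy_mean` and concentration `efficacy_dispersion` (shape parameters
#' `mean * conc` and `(1 - mean) * conc`); `efficacy_mean = 1` (or an infinite
#' concentration) degenerates to a point mass. Control guides always have
#' efficacy 0.
#'
#' @param coverage cells per guide at library construction (default 1000).
#' @param n_rounds consecutive positive-selection rounds (default 3).
#' @param capture_base background capture probability per cell (default 0.05,
#'   typical nonspecific carryover of magnetic-column selection).
#' @param capture_max capture probability of a fully activated cell carrying a
#'   strength-1 receptor guide (default 0.15; bead avidity and column capture
#'   efficiency folded in, giving the modest first-round / strong later-round
#'   enrichment characteristic of consecutive MACS selections).
#' @param efficacy_dispersion Beta concentration of guide efficacy (default 4,
#'   i.e. Beta(2, 2) at the default mean).
#' @param efficacy_mean mean guide activation efficacy (default 0.5).
#' @param sequencing_depth reads per sequenced sample (default 5e6).
#' @param abundance_cv coefficient of variation of initial guide abundance
#'   (default 0.5; 0 gives a perfectly uniform library).
#' @param seed RNG seed used by [simulate_screen()].
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(coverage = 1000, n_rounds = 3, capture_base = 0.05,
                       capture_max = 0.15, efficacy_dispersion = 4,
                       efficacy_mean = 0.5, sequencing_depth = 5e6,
                       abundance_cv = 0.5, seed = 1L) {
  if (coverage < 1) stop("coverage must be >= 1")
  if (n_rounds < 1) stop("n_rounds must be >= 1")
  if (capture_base < 0 || capture_max > 1 || capture_base > capture_max)
    stop("need 0 <= capture_base <= capture_max <= 1")
  if (sequencing_depth < 1) stop("sequencing_depth must be >= 1")
  if (abundance_cv < 0) stop("abundance_cv must be >= 0")
  if (efficacy_mean < 0 || efficacy_mean > 1)
    stop("efficacy_mean must lie in [0, 1]")
  if (efficacy_dispersion <= 0) stop("efficacy_dispersion must be > 0")
  structure(
    list(coverage = coverage, n_rounds = as.integer(n_rounds),
         capture_base = capture_base, capture_max = capture_max,
         efficacy_dispersion = efficacy_dispersion,
         efficacy_mean = efficacy_mean,
         sequencing_depth = sequencing_depth,
         abundance_cv = abundance_cv, seed = as.integer(seed)),
    class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Screen simulation parameters\n")
  cat(sprintf("  coverage %g cells/guide, %d selection rounds, depth %g reads\n",
              x$coverage, x$n_rounds, x$sequencing_depth))
  cat(sprintf("  capture: base %.3g, max %.3g; efficacy Beta(mean %.2g, conc %.2g); abundance CV %.2g\n",
              x$capture_base, x$capture_max, x$efficacy_mean,
              x$efficacy_dispersion, x$abundance_cv))
  invisible(x)
}
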