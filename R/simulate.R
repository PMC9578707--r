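#' Build the naive library cell population
#'
#' Instantiates the cell population for a screen design: per-guide cell counts
#' drawn around `coverage` cells/guide from a right-skewed log-normal
#' distribution with coefficient of variation `abundance_cv` (lentiviral
#' pooled libraries are right-skewed), and a per-guide activation efficacy.
#' Gene-targeting guides draw efficacy from the Beta model in [sim_params()];
#' control guides (half safe-targeting, half non-targeting) have efficacy 0.
#'
#' @param design a [screen_design()].
#' @param params a [sim_params()].
#' @return An object of class `screen_population`: guide metadata, per-guide
#'   cell counts, per-guide efficacies and per-gene binding strengths.
#' @export
build_library <- function(design, params) {
  stopifnot(inherits(design, "screen_design"), inherits(params, "sim_params"))
  n_gene_guides <- length(design$gene_ids) * design$guides_per_gene
  if (n_gene_guides < 1L) stop("design contains no guides")

  gene_guide_ids <- paste0(rep(design$gene_ids, each = design$guides_per_gene),
                           "_sg", sprintf("%02d", seq_len(design$guides_per_gene)))
  guide_gene <- rep(design$gene_ids, each = design$guides_per_gene)
  category <- rep("gene", n_gene_guides)
  if (design$n_controls > 0L) {
    n_safe <- ceiling(design$n_controls / 2)
    ctrl_cat <- c(rep("safe", n_safe), rep("nontargeting", design$n_controls - n_safe))
    ctrl_ids <- paste0("CTRL_sg", sprintf("%04d", seq_len(design$n_controls)))
    gene_guide_ids <- c(gene_guide_ids, ctrl_ids)
    guide_gene <- c(guide_gene, rep("control", design$n_controls))
    category <- c(category, ctrl_cat)
  }
  n_guides <- length(gene_guide_ids)

  # initial abundance: log-normal with mean `coverage`, CV `abundance_cv`
  if (params$abundance_cv > 0) {
    sdlog <- sqrt(log1p(params$abundance_cv^2))
    cells <- round(params$coverage *
                     stats::rlnorm(n_guides, meanlog = -sdlog^2 / 2, sdlog = sdlog))
  } else {
    cells <- rep(round(params$coverage), n_guides)
  }
  cells <- pmax(cells, 0)

  efficacy <- numeric(n_guides)
  is_gene <- category == "gene"
  if (params$efficacy_mean >= 1 || !is.finite(params$efficacy_dispersion)) {
    efficacy[is_gene] <- params$efficacy_mean
  } else if (params$efficacy_mean <= 0) {
    efficacy[is_gene] <- 0
  } else {
    a <- params$efficacy_mean * params$efficacy_dispersion
    b <- (1 - params$efficacy_mean) * params$efficacy_dispersion
    efficacy[is_gene] <- stats::rbeta(sum(is_gene), a, b)
  }

  strength <- numeric(n_guides)
  if (length(design$true_receptors)) {
    idx <- match(guide_gene, names(design$true_receptors))
    strength[!is.na(idx)] <- design$true_receptors[idx[!is.na(idx)]]
  }

  structure(
    list(guide_id = gene_guide_ids, gene_id = guide_gene, category = category,
         cells = as.numeric(cells), efficacy = efficacy, strength = strength,
         design = design, params = params),
    class = "screen_population")
}

#' @export
print.screen_population <- function(x, ...) {
  cat(sprintf("Screen population: %d guides, %.3g cells (%.0f/guide mean)\n",
              length(x$guide_id), sum(x$cells), mean(x$cells)))
  invisible(x)
}

#' Simulate one round of magnetic-bead positive selection
#'
#' Each cell is retained on the beads independently with probability
#' `p = capture_base + (capture_max - capture_base) * efficacy * strength`,
#' where efficacy is the guide's CRISPRa activation efficacy and strength the
#' binding strength of its target gene (0 for non-receptors and controls).
#' The captured cells are then expanded back to the pre-selection population
#' size by multinomial resampling of the post-capture composition.
#'
#' Uses the current RNG state; seed upstream (or via [simulate_screen()]).
#'
#' @param population a `screen_population` from [build_library()].
#' @return The population after selection and expansion.
#' @export
simulate_selection_round <- function(population) {
  stopifnot(inherits(population, "screen_population"))
  n_total <- sum(population$cells)
  if (n_total <= 0) stop("population is empty; nothing to select")
  p <- population$params$capture_base +
    (population$params$capture_max - population$params$capture_base) *
    population$efficacy * population$strength
  captured <- stats::rbinom(length(population$cells),
                            size = round(population$cells), prob = p)
  if (sum(captured) == 0)
    stop("selection captured zero cells (capture probabilities too low for ",
         "this population size); increase capture_base or coverage")
  expanded <- stats::rmultinom(1, size = round(n_total),
                               prob = captured / sum(captured))[, 1]
  population$cells <- as.numeric(expanded)
  population
}

#' Simulate sequencing of a cell population
#'
#' Draws read counts as a multinomial sample of size `depth` over the current
#' guide frequencies, modeling the PCR/deep-sequencing readout. Counts sum to
#' `depth` exactly.
#'
#' @param population a `screen_population`.
#' @param depth reads to draw (>= 1).
#' @return Named integer vector of per-guide read counts.
#' @export
simulate_sequencing <- function(population, depth) {
  stopifnot(inherits(population, "screen_population"))
  if (depth < 1) stop("sequencing depth must be >= 1")
  if (sum(population$cells) <= 0) stop("population is empty; cannot sequence")
  counts <- stats::rmultinom(1, size = round(depth),
                             prob = population$cells / sum(population$cells))[, 1]
  stats::setNames(as.integer(counts), population$guide_id)
}

#' Simulate a complete multi-round enrichment screen
#'
#' Orchestrates [build_library()], `n_rounds` of [simulate_selection_round()],
#' and [simulate_sequencing()] of the naive population (round 0, the baseline)
#' and of each post-selection population. Fully reproducible from
#' `params$seed`.
#'
#' @param design a [screen_design()].
#' @param params a [sim_params()].
#' @return An object of class `simulated_screen`: `$counts` (a [count_table]
#'   with samples `R0 ... Rn`), `$truth` (per-guide efficacies, per-gene
#'   strengths, seed), `$design`, `$params`.
#' @examples
#' scr <- simulate_screen(
#'   screen_design(paste0("G", 1:20), n_controls = 20,
#'                 true_receptors = c(G1 = 1)),
#'   sim_params(n_rounds = 2, sequencing_depth = 1e5, seed = 7))
#' scr$counts
#' @export
simulate_screen <- function(design, params) {
  stopifnot(inherits(design, "screen_design"), inherits(params, "sim_params"))
  set.seed(params$seed)
  pop <- build_library(design, params)
  samples <- paste0("R", 0:params$n_rounds)
  counts <- matrix(0L, nrow = length(pop$guide_id), ncol = length(samples),
                   dimnames = list(pop$guide_id, samples))
  counts[, 1L] <- simulate_sequencing(pop, params$sequencing_depth)
  for (r in seq_len(params$n_rounds)) {
    pop <- simulate_selection_round(pop)
    counts[, r + 1L] <- simulate_sequencing(pop, params$sequencing_depth)
  }
  lib <- data.frame(guide_id = pop$guide_id, gene_id = pop$gene_id,
                    category = pop$category, stringsAsFactors = FALSE)
  ct <- count_table(counts, lib,
                    samples = data.frame(sample_id = samples,
                                         round = 0:params$n_rounds))
  structure(
    list(counts = ct,
         truth = list(efficacy = stats::setNames(pop$efficacy, pop$guide_id),
                      strength = design$true_receptors, seed = params$seed),
         design = design, params = params),
    class = "simulated_screen")
}

#' @export
print.simulated_screen <- function(x, ...) {
  cat(sprintf("Simulated CRISPRa screen [%s]: %d guides, %d samples (naive + %d rounds)\n",
              x$design$library_label, nrow(x$counts$counts),
              ncol(x$counts$counts), x$params$n_rounds))
  invisible(x)
}

#' Write simulated ground truth as JSON
#'
#' @param screen a `simulated_screen`.
#' @param path output file.
#' @export
write_ground_truth <- function(screen, path) {
  stopifnot(inherits(screen, "simulated_screen"))
  jsonlite::write_json(
    list(seed = screen$truth$seed,
         strength = as.list(screen$truth$strength),
         efficacy = as.list(screen$truth$efficacy)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
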