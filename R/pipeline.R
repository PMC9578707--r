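#' Run a complete screen analysis
#'
#' End-to-end orchestration: obtain counts (either simulate a screen from a
#' design or read a count-table TSV), analyze every selection round against
#' the naive round-0 baseline, call hits with the first-pass filter and
#' trajectory classification, and write results, rank-plot and
#' trajectory-plot data, and a manifest recording parameters and seeds.
#' Deterministic given the seeds in the config.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{counts}{path to a count-table TSV (alternative to `simulate`).}
#'     \item{simulate}{list with `design` (fields of [screen_design()]) and
#'       `params` (fields of [sim_params()]).}
#'     \item{annotation}{path to a TSV with columns `gene_id`, `class`, or a
#'       named vector. When absent every gene is classed `"other"` (a warning
#'       is emitted, and no gene can then pass the proteome filter).}
#'     \item{blacklist}{character vector or path to a one-column file.}
#'     \item{analysis}{fields of [analysis_config()].}
#'     \item{output_dir}{directory for result files (created; optional).}
#'   }
#' @return List with `counts`, `rounds` (per-round `gene_results`), `hits`,
#'   and `manifest`, invisibly written to `output_dir` when given.
#' @export
run_screen_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))

  if (!is.null(config$counts)) {
    ct <- read_count_table(config$counts)
    truth <- NULL
  } else if (!is.null(config$simulate)) {
    des <- do.call(screen_design, config$simulate$design)
    par <- do.call(sim_params, as.list(config$simulate$params))
    scr <- simulate_screen(des, par)
    ct <- scr$counts
    truth <- scr$truth
  } else {
    stop("config must provide either 'counts' or 'simulate'")
  }

  annotation <- config$annotation
  if (is.character(annotation) && length(annotation) == 1L &&
      file.exists(annotation)) {
    adf <- utils::read.delim(annotation, stringsAsFactors = FALSE)
    annotation <- stats::setNames(adf$class, adf$gene_id)
  }
  if (is.null(annotation))
    warning("no annotation supplied: all genes classed 'other'; ",
            "no gene can pass the membrane/secreted-proteome filter")
  blacklist <- config$blacklist
  if (is.character(blacklist) && length(blacklist) == 1L &&
      file.exists(blacklist))
    blacklist <- readLines(blacklist)
  if (is.null(blacklist)) blacklist <- character()

  acfg <- do.call(analysis_config, as.list(config$analysis))
  samples <- ct$samples
  ref <- samples$sample_id[which.min(samples$round)]
  sel <- samples$sample_id[order(samples$round)][-1]
  rounds <- lapply(sel, function(s) analyze_round(ct, s, ref, acfg))
  names(rounds) <- sel

  hits <- if (length(rounds) >= 2)
    call_hits(rounds, annotation, blacklist,
              p_floor = 1 / (acfg$n_perm + 1))
  else NULL

  manifest <- list(
    package = "deorphan",
    version = as.character(utils::packageVersion("deorphan")),
    samples = samples, reference = ref,
    analysis = acfg[c("pseudocount", "n_perm", "n_trapz", "seed")],
    grid = range(acfg$grid),
    simulation_seed = if (!is.null(truth)) truth$seed else NULL,
    n_guides = nrow(ct$counts),
    n_genes = length(unique(ct$library$gene_id[ct$library$category == "gene"])),
    blacklist = blacklist)

  out <- list(counts = ct, rounds = rounds, hits = hits, truth = truth,
              manifest = manifest)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$output_dir, f)
    write_count_table(ct, p("counts.tsv"))
    write_gene_results(rounds, p("gene_results.tsv"))
    if (!is.null(hits)) {
      write_hits(hits, p("hits.tsv"))
      utils::write.table(hits[, c("rank", "gene", "esp")], p("rank_plot.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      traj_cols <- grep("^esp_R", names(hits), value = TRUE)
      utils::write.table(hits[, c("gene", traj_cols)], p("trajectories.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  }
  invisible(out)
}

#' Write the packaged example fixtures
#'
#' Deterministically writes: the 22-edge validated-interaction fixture
#' ([validated_interactions()]), the 10-target x 10-sgRNA mini-library design with 100
#' matched controls, a small synthetic protein family FASTA, and a small
#' synthetic expression matrix. Rerunning overwrites identically.
#'
#' @param output_dir target directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
make_fixtures <- function(output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = file.path(output_dir, "validated_interactions.tsv"),
             library = file.path(output_dir, "mini_library.tsv"),
             fasta = file.path(output_dir, "synthetic_family.fa"),
             expression = file.path(output_dir, "synthetic_expression.tsv"))

  write_edges(validated_interactions(), paths[["edges"]])

  des <- mini_library_design()
  lib <- build_fixture_library(des)
  write_guide_library(lib, paths[["library"]])

  fam <- synthetic_family()
  writeLines(paste0(">", names(fam), "\n", unname(fam)), paths[["fasta"]])

  write_expression(synthetic_expression(), paths[["expression"]])
  paths
}

#' The benchmark mini-library design
#'
#' Ten targets with 10 sgRNAs each (100 gene-targeting guides) matched with
#' 100 control guides, the design used to validate the screening workflow
#' with a single known receptor (target `TGT01`) spiked in.
#'
#' @return A [screen_design()].
#' @export
mini_library_design <- function() {
  screen_design(sprintf("TGT%02d", 1:10), guides_per_gene = 10,
                n_controls = 100, true_receptors = c(TGT01 = 1),
                library_label = "mini")
}

# Expand a design into a guide-library table (no population state).
build_fixture_library <- function(design) {
  pop <- build_library(design, sim_params(abundance_cv = 0, coverage = 1))
  data.frame(guide_id = pop$guide_id, gene_id = pop$gene_id,
             category = pop$category, stringsAsFactors = FALSE)
}

# Small synthetic protein family: one conserved core with increasing numbers
# of substitutions, labelled synthetic (not real receptor sequences).
synthetic_family <- function() {
  c(SYNF1 = "MKTLLVAAGLLACSQAWNVNTTESPGKLQVLQ",
    SYNF2 = "MKTLLVAAGLLACSQAWNVNTTESPGKLRVLQ",
    SYNF3 = "MKTLLVAGGLLTCSQAWNVDTTKSPGKLRVLQ",
    SYNF4 = "MRSLIVGGGILTCAQGWHVDSTKAPGRLRILE",
    SYNOUT = "GGGGGPPPPPWWWWWHHHHHKKKKKEEEEEDD")
}

# Small synthetic genes x tissues expression matrix with two co-expressed
# blocks, used for clustering examples.
synthetic_expression <- function() {
  tissues <- c("brain", "heart", "liver", "lung", "kidney", "muscle",
               "spleen", "skin")
  base <- rbind(
    SYNA1 = c(9, 1, 1, 2, 1, 1, 2, 1),
    SYNA2 = c(8, 2, 1, 2, 1, 1, 2, 2),
    SYNA3 = c(7, 1, 2, 3, 1, 2, 1, 1),
    SYNB1 = c(1, 8, 7, 1, 2, 9, 1, 1),
    SYNB2 = c(2, 7, 8, 1, 1, 8, 2, 1),
    SYNC1 = c(3, 3, 3, 3, 3, 3, 3, 9))
  colnames(base) <- tissues
  base
}
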