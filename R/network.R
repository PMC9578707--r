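#' Construct a set of ligand-receptor interaction edges
#'
#' Edges are unordered ligand-receptor pairs annotated with the screening
#' library (`TM1` or `TM2+`), the discovery source (`Screen` for a direct
#' CRISPRa enrichment hit, `PHA` for phylogenetic-homology expansion), and
#' the validation assays (`SPR`, `CSS`). Symbols are uppercased; duplicate
#' unordered pairs are rejected.
#'
#' @param ligand,receptor character vectors of gene symbols.
#' @param library `"TM1"` or `"TM2+"` per edge.
#' @param source `"Screen"` or `"PHA"` per edge.
#' @param assays character vector per edge, e.g. `"SPR, CSS"`.
#' @return data.frame of class `interaction_edges`.
#' @export
interaction_edges <- function(ligand, receptor, library, source,
                              assays = NA_character_) {
  df <- data.frame(ligand = toupper(as.character(ligand)),
                   receptor = toupper(as.character(receptor)),
                   library = as.character(library),
                   source = as.character(source),
                   assays = as.character(assays), stringsAsFactors = FALSE)
  bad <- setdiff(df$library, c("TM1", "TM2+"))
  if (length(bad)) stop("unknown library: ", paste(bad, collapse = ", "))
  bad <- setdiff(df$source, c("Screen", "PHA"))
  if (length(bad)) stop("unknown source: ", paste(bad, collapse = ", "))
  key <- pair_key(df$ligand, df$receptor)
  if (anyDuplicated(key))
    stop("duplicate interaction pair: ", key[duplicated(key)][1])
  class(df) <- c("interaction_edges", "data.frame")
  df
}

pair_key <- function(a, b) {
  paste(pmin(toupper(a), toupper(b)), pmax(toupper(a), toupper(b)), sep = "|")
}

#' Read / write interaction edges as TSV
#'
#' @param path TSV with columns `ligand`, `receptor`, `library`, `source`,
#'   `assays`.
#' @return An `interaction_edges` data.frame.
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  interaction_edges(df$ligand, df$receptor, df$library, df$source,
                    if ("assays" %in% names(df)) df$assays else NA)
}

#' @rdname read_edges
#' @param edges an `interaction_edges` data.frame.
#' @export
write_edges <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Summarize a ligand-receptor interaction network
#'
#' Exact set arithmetic over the edge list: total edges, edges by library and
#' by source, distinct ligands (screens) overall and per library, and node
#' lists.
#'
#' @param edges an [interaction_edges()] data.frame.
#' @return An object of class `network_summary`.
#' @examples
#' net <- build_network(validated_interactions())
#' net
#' @export
build_network <- function(edges) {
  if (!nrow(edges)) {
    return(structure(list(n_edges = 0L,
                          by_library = c("TM1" = 0L, "TM2+" = 0L),
                          by_source = c(Screen = 0L, PHA = 0L),
                          n_ligands = 0L,
                          ligands_by_library = c("TM1" = 0L, "TM2+" = 0L),
                          ligands = character(), receptors = character(),
                          nodes = character(), edges = edges),
                     class = "network_summary"))
  }
  key <- pair_key(edges$ligand, edges$receptor)
  if (anyDuplicated(key))
    stop("duplicate unordered pair in edge list: ", key[duplicated(key)][1])
  lib_counts <- sapply(c("TM1", "TM2+"), function(l) sum(edges$library == l))
  src_counts <- sapply(c("Screen", "PHA"), function(s) sum(edges$source == s))
  ligands <- unique(edges$ligand)
  lig_by_lib <- sapply(c("TM1", "TM2+"), function(l)
    length(unique(edges$ligand[edges$library == l])))
  structure(
    list(n_edges = nrow(edges), by_library = lib_counts,
         by_source = src_counts, n_ligands = length(ligands),
         ligands_by_library = lig_by_lib, ligands = ligands,
         receptors = unique(edges$receptor),
         nodes = unique(c(edges$ligand, edges$receptor)), edges = edges),
    class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("Ligand-receptor network: %d interactions (%d TM1, %d TM2+; %d Screen, %d PHA)\n",
              x$n_edges, x$by_library[["TM1"]], x$by_library[["TM2+"]],
              x$by_source[["Screen"]], x$by_source[["PHA"]]))
  cat(sprintf("  %d distinct ligand screens (%d TM1, %d TM2+), %d receptors, %d nodes\n",
              x$n_ligands, x$ligands_by_library[["TM1"]],
              x$ligands_by_library[["TM2+"]],
              length(x$receptors), length(x$nodes)))
  invisible(x)
}

#' The packaged validated-interaction fixture
#'
#' The 22 validated ligand-receptor interactions underlying the network
#' summary: 18 from the single-pass (TM1) library across 8 ligand screens and
#' 4 from the multi-pass (TM2+) library across 4 ligand screens, each tagged
#' with its discovery source (direct screen hit vs phylogenetic-homology
#' expansion) and validation assays.
#'
#' @return An [interaction_edges()] data.frame with 22 rows.
#' @export
validated_interactions <- function() {
  interaction_edges(
    ligand = c("GAS1", "OMG", "OMG", "OMG", "OMG", "OSTN", "MK", "PTN", "PTN",
               "PTN", "SMOC1", "SMOC1", "TAFA2", "TAFA2", "TAFA2", "TAFA2",
               "TAFA2", "TAFA5", "LY6H", "NRN1", "SCRG1", "VWC2L"),
    receptor = c("PTPRA", "PTPRD", "PTPRF", "PTPRS", "PTPRU", "PTPRU",
                 "RNF167", "RNF167", "ROR1", "MFRP", "SMOC1", "SMOC2",
                 "KIR3DL1", "KIR3DL2", "KIR3DL3", "KIR2DL5A", "RNF167",
                 "RNF167", "CD36", "CD36", "CD36", "CD36"),
    library = c(rep("TM1", 18), rep("TM2+", 4)),
    source = c("Screen", "PHA", "PHA", "PHA", "Screen", "Screen", "Screen",
               "Screen", "Screen", "Screen", "PHA", "Screen", "Screen",
               "PHA", "Screen", "PHA", "Screen", "Screen", "Screen",
               "Screen", "Screen", "Screen"),
    assays = c("SPR, CSS", "SPR", "SPR", "SPR", "SPR", "SPR", "SPR", "SPR",
               "SPR", "SPR", "SPR", "SPR", "SPR, CSS", "SPR, CSS", "CSS",
               "CSS", "SPR", "SPR", "CSS", "CSS", "CSS", "CSS"))
}

#' Overlap of an edge set with external interaction databases
#'
#' Normalizes every edge to an unordered uppercase pair and computes, for
#' each external set, the intersection with the study edges, plus the sizes
#' of every region of the Venn partition over all sets (study included).
#'
#' @param edges an `interaction_edges` data.frame or two-column matrix/df.
#' @param external named list of edge sets (each a two-column object or an
#'   `interaction_edges`).
#' @return List with `per_set` (named intersection counts with the study
#'   set) and `venn` (named vector over membership patterns like
#'   `study&BioGRID`).
#' @export
database_overlap <- function(edges, external) {
  sets <- c(list(study = edge_keys(edges)), lapply(external, edge_keys))
  universe <- unique(unlist(sets))
  member <- sapply(sets, function(s) universe %in% s)
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, names(sets)))
  per_set <- sapply(names(sets)[-1], function(nm)
    sum(member[, "study"] & member[, nm]))
  pattern <- apply(member, 1, function(row)
    paste(colnames(member)[row], collapse = "&"))
  venn <- table(pattern)
  list(per_set = per_set, venn = stats::setNames(as.integer(venn), names(venn)))
}

edge_keys <- function(x) {
  if (is.data.frame(x) && all(c("ligand", "receptor") %in% names(x)))
    return(unique(pair_key(x$ligand, x$receptor)))
  x <- as.matrix(x)
  unique(pair_key(x[, 1], x[, 2]))
}

#' Export a network as GraphML
#'
#' Minimal GraphML writer for the edge list (nodes typed ligand/receptor,
#' edges carrying library and source attributes), for use in Cytoscape-like
#' viewers.
#'
#' @param edges an `interaction_edges` data.frame.
#' @param path output file.
#' @export
write_graphml <- function(edges, path) {
  nodes <- unique(c(edges$ligand, edges$receptor))
  type <- ifelse(nodes %in% edges$ligand, "ligand", "receptor")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="type" for="node" attr.name="type" attr.type="string"/>',
    '  <key id="library" for="edge" attr.name="library" attr.type="string"/>',
    '  <key id="source" for="edge" attr.name="source" attr.type="string"/>',
    '  <graph edgedefault="undirected">'), con)
  writeLines(sprintf('    <node id="%s"><data key="type">%s</data></node>',
                     nodes, type), con)
  writeLines(sprintf(
    '    <edge source="%s" target="%s"><data key="library">%s</data><data key="source">%s</data></edge>',
    edges$ligand, edges$receptor, edges$library, edges$source), con)
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}
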