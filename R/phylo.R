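#' Pairwise protein identity from global alignment
#'
#' Needleman-Wunsch global alignment with a substitution matrix and affine
#' gaps; identity is the number of identical aligned positions divided by the
#' alignment length (gap columns included).
#'
#' @param seq_a,seq_b amino-acid sequences (single-letter code).
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (defaults 10, 1).
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(seq_a, seq_b, matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 1) {
  check_protein(seq_a)
  check_protein(seq_b)
  sm <- get_submat(matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = sm, gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(a == b & a != "-") / length(a)
}

check_protein <- function(s) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop("sequences must be non-empty single strings")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYBXZJUO*]", toupper(s)))
    stop("invalid amino-acid residues in sequence")
  invisible(s)
}

get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Pairwise alignment distance matrix
#'
#' `d(a, b) = 1 - identity(a, b)` for every sequence pair; symmetric with a
#' zero diagonal.
#'
#' @param sequences named character vector (or `AAStringSet`) of protein
#'   sequences.
#' @inheritParams pairwise_identity
#' @return Symmetric numeric matrix with the sequence names as labels.
#' @export
distance_matrix <- function(sequences, matrix = "BLOSUM62", gap_open = 10,
                            gap_extend = 1) {
  nms <- names(sequences)
  sequences <- as.character(sequences)
  names(sequences) <- nms
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names")
  n <- length(sequences)
  D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- 1 - pairwise_identity(sequences[[i]], sequences[[j]], matrix,
                                   gap_open, gap_extend)
        D[i, j] <- d
        D[j, i] <- d
      }
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Builds an unrooted neighbor-joining tree; on additive distance matrices
#' the tree's path lengths reproduce the input distances exactly. Negative
#' branch lengths (which NJ can produce on non-additive input) are clamped
#' to zero.
#'
#' @param D symmetric distance matrix with labels (or a [stats::dist]).
#' @return An [ape::nj] `phylo` tree (serializable to newick with
#'   [ape::write.tree]).
#' @export
nj_tree <- function(D) {
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-12)
      stop("distance matrix must be symmetric")
    if (any(diag(D) != 0)) stop("distance matrix must have a zero diagonal")
    D <- stats::as.dist(D)
  }
  if (attr(D, "Size") < 3) stop("neighbor joining needs >= 3 labels")
  tree <- ape::nj(D)
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Phylogenetic-homology candidate expansion
#'
#' Given a validated receptor and its protein family, returns the family
#' members within alignment distance `delta` of the validated seed - the
#' candidates that homology predicts may share the ligand. The seed itself is
#' excluded; candidates are sorted by distance.
#'
#' @param validated_receptor label of the validated family member.
#' @param family named character vector of family protein sequences (must
#'   include the seed), or a precomputed distance matrix.
#' @param delta maximum alignment distance (`1 - identity`) for a candidate
#'   (default 0.6, separating within- from between-subfamily distances).
#' @inheritParams pairwise_identity
#' @return data.frame with columns `candidate`, `distance`.
#' @export
pha_candidates <- function(validated_receptor, family, delta = 0.6,
                           matrix = "BLOSUM62", gap_open = 10,
                           gap_extend = 1) {
  D <- if (is.matrix(family)) family
       else distance_matrix(family, matrix, gap_open, gap_extend)
  if (!validated_receptor %in% rownames(D))
    stop("validated receptor '", validated_receptor, "' not in family")
  d <- D[validated_receptor, ]
  d <- d[names(d) != validated_receptor]
  d <- sort(d[d <= delta])
  data.frame(candidate = names(d), distance = unname(d),
             stringsAsFactors = FALSE)
}
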