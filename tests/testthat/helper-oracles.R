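# Independent oracles used across the suite. These re-derive expected values
# by brute force or closed form and never call the code paths they check.

# --- global alignment: exhaustive enumeration with affine gaps -------------
# Enumerates every global alignment of two short sequences, scoring gaps as
# open + len * ext per contiguous gap run, and returns the optimal score and
# the set of identity fractions achieved by optimal alignments.
brute_force_alignment <- function(a, b, submat, open = 10, ext = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$identities <- numeric()
  recurse <- function(i, j, cols) {
    if (i > length(a) && j > length(b)) {
      sc <- 0
      run <- 0  # signed gap run tracker: +1 gap in b, -1 gap in a
      nid <- 0
      for (cl in cols) {
        if (cl[1] == "-" || cl[2] == "-") {
          cur <- if (cl[1] == "-") -1 else 1
          sc <- sc - ext - if (run == cur) 0 else open
          run <- cur
        } else {
          sc <- sc + submat[cl[1], cl[2]]
          if (cl[1] == cl[2]) nid <- nid + 1
          run <- 0
        }
      }
      idf <- nid / length(cols)
      if (sc > best$score + 1e-9) {
        best$score <- sc
        best$identities <- idf
      } else if (abs(sc - best$score) <= 1e-9) {
        best$identities <- unique(c(best$identities, idf))
      }
      return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      recurse(i + 1, j + 1, c(cols, list(c(a[i], b[j]))))
    if (i <= length(a))
      recurse(i + 1, j, c(cols, list(c(a[i], "-"))))
    if (j <= length(b))
      recurse(i, j + 1, c(cols, list(c("-", b[j]))))
  }
  recurse(1, 1, list())
  list(score = best$score, identities = best$identities)
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# --- neighbor joining: enumeration over 4-taxon topologies -----------------
# For 4 taxa there are 3 unrooted topologies, identified by the pairing of
# the cherries. Least-squares branch lengths for topology ((a,b),(c,d)) come
# from the linear system of the 6 pairwise path lengths; returns per-topology
# residual sums of squares.
quartet_fits <- function(D) {
  stopifnot(nrow(D) == 4)
  labs <- rownames(D)
  pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  res <- lapply(pairings, function(p) {
    a <- p[1]; b <- p[2]; c <- p[3]; d <- p[4]
    # path-length design matrix for branches (ea, eb, ec, ed, internal)
    X <- rbind(c(1, 1, 0, 0, 0),   # a-b
               c(1, 0, 1, 0, 1),   # a-c
               c(1, 0, 0, 1, 1),   # a-d
               c(0, 1, 1, 0, 1),   # b-c
               c(0, 1, 0, 1, 1),   # b-d
               c(0, 0, 1, 1, 0))   # c-d
    y <- c(D[a, b], D[a, c], D[a, d], D[b, c], D[b, d], D[c, d])
    beta <- solve(crossprod(X), crossprod(X, y))
    list(cherries = list(sort(labs[c(a, b)]), sort(labs[c(c, d)])),
         rss = sum((y - X %*% beta)^2), lengths = as.numeric(beta))
  })
  res
}

# The cherry pairing of an unrooted 4-taxon phylo tree.
quartet_split <- function(tree) {
  stopifnot(length(tree$tip.label) == 4)
  internal <- which(tabulate(tree$edge[, 1]) > 0)
  # find the two tips attached to the same internal node
  for (node in unique(tree$edge[, 1])) {
    tips <- tree$edge[tree$edge[, 1] == node, 2]
    tips <- tips[tips <= 4]
    if (length(tips) == 2) return(sort(tree$tip.label[tips]))
  }
  stop("no cherry found")
}

# Additive distance matrix implied by a phylo tree (independent of ape's
# cophenetic: accumulates edge lengths over tree paths via the edge list).
tree_path_lengths <- function(tree) {
  n <- length(tree$tip.label)
  nodes <- max(tree$edge)
  adj <- vector("list", nodes)
  for (k in seq_len(nrow(tree$edge))) {
    i <- tree$edge[k, 1]; j <- tree$edge[k, 2]; w <- tree$edge.length[k]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (r in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][r, 1]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + adj[[v]][r, 2]
          queue <- c(queue, u)
        }
      }
    }
    D[s, ] <- dist[seq_len(n)]
  }
  D
}

# --- Ward clustering: naive Lance-Williams agglomeration -------------------
# Recomputes the Ward (ward.D2) merge sequence from scratch with explicit
# loops over cluster pairs; returns the list of merged label sets in order.
ward_merge_order <- function(D) {
  labs <- rownames(D)
  clusters <- as.list(labs)
  d <- D^2  # ward.D2 operates on squared dissimilarities internally
  sizes <- rep(1, length(labs))
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestval <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        if (d[i, j] < bestval - 1e-12) {
          bestval <- d[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    merges[[length(merges) + 1]] <- sort(unlist(clusters[c(i, j)]))
    ni <- sizes[i]; nj <- sizes[j]
    newrow <- sapply(seq_along(clusters), function(k) {
      if (k == i || k == j) return(NA_real_)
      nk <- sizes[k]
      ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] - nk * d[i, j]) /
        (ni + nj + nk)
    })
    keep <- setdiff(seq_along(clusters), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    clusters <- c(clusters[keep], list(unlist(merges[[length(merges)]])))
    sizes <- c(sizes[keep], ni + nj)
  }
  merges
}

# Merge order realized by an hclust object, as sorted label sets.
hclust_merge_order <- function(hc, labs) {
  members <- list()
  out <- list()
  for (k in seq_len(nrow(hc$merge))) {
    get_set <- function(v) if (v < 0) labs[-v] else members[[v]]
    s <- sort(c(get_set(hc$merge[k, 1]), get_set(hc$merge[k, 2])))
    members[[k]] <- s
    out[[k]] <- s
  }
  out
}

# --- screen helpers --------------------------------------------------------
benchmark_design <- function(n_genes = 200, n_controls = 200,
                             receptor = "G001", strength = 1) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  screen_design(genes, guides_per_gene = 10, n_controls = n_controls,
                true_receptors = stats::setNames(strength, receptor))
}

membrane_annotation <- function(genes) {
  stats::setNames(rep("TM1-membrane", length(genes)), genes)
}

# Closed-form one-step frequency update under per-cell Bernoulli capture.
expected_freq_after_round <- function(freq, p_capture) {
  w <- freq * p_capture
  w / sum(w)
}
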