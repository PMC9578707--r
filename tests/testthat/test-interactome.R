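test_that("network summary counts the validated-interaction fixture exactly", {
  edges <- validated_interactions()
  net <- build_network(edges)
  expect_equal(net$n_edges, 22)
  expect_equal(unname(net$by_library), c(18, 4))
  expect_equal(net$n_ligands, 12)
  expect_equal(unname(net$ligands_by_library), c(8, 4))

  # counts invariant to edge order and to swapping the pair columns
  shuf <- edges[sample(nrow(edges)), ]
  net2 <- build_network(shuf)
  expect_equal(net2$n_edges, net$n_edges)
  expect_equal(net2$by_library, net$by_library)
  swapped <- edges
  swapped$ligand <- edges$receptor
  swapped$receptor <- edges$ligand
  expect_equal(build_network(swapped)$n_edges, 22)

  expect_equal(build_network(edges[0, ])$n_edges, 0)
  dup <- rbind(as.data.frame(edges),
               data.frame(ligand = "PTPRA", receptor = "GAS1",
                          library = "TM1", source = "Screen", assays = "SPR"))
  expect_error(build_network(dup), "duplicate")
  expect_error(interaction_edges("A", "B", "TM9", "Screen"), "library")
})

test_that("edges round-trip through TSV and GraphML export is well-formed", {
  edges <- validated_interactions()
  path <- tempfile(fileext = ".tsv")
  write_edges(edges, path)
  expect_equal(as.data.frame(read_edges(path)), as.data.frame(edges))

  gml <- tempfile(fileext = ".graphml")
  write_graphml(edges, gml)
  doc <- readLines(gml)
  expect_equal(sum(grepl("<edge ", doc)), 22)
  expect_equal(sum(grepl("<node ", doc)), length(build_network(edges)$nodes))
})

test_that("pairwise identity agrees with exhaustive alignment enumeration", {
  expect_equal(pairwise_identity("MKTLLVAAGL", "MKTLLVAAGL"), 1.0)
  sm <- blosum62()
  for (pair in list(c("ACDE", "EDCA"), c("AAAA", "WWWW"), c("WCDE", "WDE"),
                    c("KRDE", "KRRDE"))) {
    oracle <- brute_force_alignment(pair[1], pair[2], sm)
    expect_true(pairwise_identity(pair[1], pair[2]) %in% oracle$identities,
                info = paste(pair, collapse = " vs "))
  }
  # match-free optimal alignment of disjoint alphabets has identity 0
  expect_equal(pairwise_identity("AAAA", "WWWW"), 0)
  expect_error(pairwise_identity("AC1E", "ACDE"), "invalid")
})

test_that("distance matrices are semimetric and compose from pairwise calls", {
  seqs <- c(a = "MKTLLVAAGL", b = "MKTLLVAGGL", c = "WWPPHHKKEE")
  D <- distance_matrix(seqs)
  expect_equal(diag(D), c(a = 0, b = 0, c = 0))
  expect_equal(D, t(D))
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D["a", "b"], 1 - pairwise_identity(seqs["a"], seqs["b"]))
  expect_equal(D["a", "c"], 1 - pairwise_identity(seqs["a"], seqs["c"]))
})

test_that("neighbor joining reproduces additive trees exactly", {
  # 3 taxa: closed-form three-point branch lengths
  D3 <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  bl <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(bl[["a"]], (5 + 9 - 10) / 2)
  expect_equal(bl[["b"]], (5 + 10 - 9) / 2)
  expect_equal(bl[["c"]], (9 + 10 - 5) / 2)

  # 4 taxa from a known tree: topology matches the least-squares minimum
  # over all 3 enumerated topologies, path lengths reproduced to 1e-9
  set.seed(11)
  tr <- ape::rtree(4, br = function(n) runif(n, 0.1, 1))
  D4 <- tree_path_lengths(tr)
  fit <- nj_tree(D4)
  expect_lt(max(abs(tree_path_lengths(fit)[rownames(D4), colnames(D4)] - D4)),
            1e-9)
  fits <- quartet_fits(D4)
  best <- fits[[which.min(sapply(fits, `[[`, "rss"))]]
  expect_true(list(quartet_split(fit)) %in% best$cherries)

  # ultrametric input: NJ respects the single-linkage hierarchy
  DU <- matrix(c(0, 2, 8, 8,
                 2, 0, 8, 8,
                 8, 8, 0, 4,
                 8, 8, 4, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tu <- nj_tree(DU)
  expect_lt(max(abs(tree_path_lengths(tu)[letters[1:4], letters[1:4]] - DU)),
            1e-9)
  sl <- hclust(as.dist(DU), method = "single")
  first_merge <- sort(letters[1:4][-sl$merge[1, ]])
  # the NJ cherry either is the single-linkage first merge or its complement
  expect_true(identical(quartet_split(tu), first_merge) ||
                identical(quartet_split(tu),
                          sort(setdiff(letters[1:4], first_merge))))

  bad <- D4
  bad[1, 2] <- bad[1, 2] + 1
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(D3[1:2, 1:2]), ">= 3")
  expect_true(all(nj_tree(D4)$edge.length >= 0))

  # newick serialization round-trips the leaf set
  nwk <- tempfile(fileext = ".nwk")
  ape::write.tree(fit, nwk)
  expect_setequal(ape::read.tree(nwk)$tip.label, rownames(D4))
})

test_that("homology candidate expansion respects the distance threshold", {
  D <- matrix(0, 4, 4, dimnames = list(c("seed", "n1", "n2", "far"),
                                       c("seed", "n1", "n2", "far")))
  D["seed", c("n1", "n2", "far")] <- c(0.2, 0.5, 0.9)
  D[c("n1", "n2", "far"), "seed"] <- c(0.2, 0.5, 0.9)
  D["n1", "n2"] <- D["n2", "n1"] <- 0.4
  D["n1", "far"] <- D["far", "n1"] <- 0.8
  D["n2", "far"] <- D["far", "n2"] <- 0.7

  expect_equal(pha_candidates("seed", D, delta = 0.6)$candidate, c("n1", "n2"))
  expect_equal(nrow(pha_candidates("seed", D, delta = 0)), 0)
  expect_equal(nrow(pha_candidates("seed", D, delta = 1)), 3)
  expect_error(pha_candidates("missing", D), "not in family")

  # end to end on sequences: closest family members come back first
  fam <- c(PTPX1 = "MKTLLVAAGLLACSQAWNVNTT", PTPX2 = "MKTLLVAAGLLACSQAWNVNTA",
           PTPX3 = "MKTLIVAGGLLTCAQAWHVDTT", OUT = "GGGGGPPPPPWWWWWHHHHHKK")
  cand <- pha_candidates("PTPX1", fam, delta = 0.6)
  expect_equal(cand$candidate[1], "PTPX2")
  expect_false("OUT" %in% cand$candidate)
})

test_that("Ward/correlation clustering matches a naive agglomeration oracle", {
  set.seed(21)
  expr <- matrix(runif(5 * 8, 1, 10), 5, 8,
                 dimnames = list(paste0("g", 1:5), paste0("t", 1:8)))
  hc <- hierarchical_cluster(expr, axis = "genes")
  D <- as.matrix(1 - cor(t(expr)))
  oracle <- ward_merge_order(D)
  got <- hclust_merge_order(hc$genes$hclust, rownames(expr))
  expect_equal(got, oracle)

  # identical rows merge first at height 0
  expr2 <- expr
  expr2[2, ] <- expr2[1, ]
  hc2 <- hierarchical_cluster(expr2, axis = "genes")
  expect_equal(sort(hclust_merge_order(hc2$genes$hclust,
                                       rownames(expr2))[[1]]), c("g1", "g2"))
  expect_equal(hc2$genes$hclust$height[1], 0, tolerance = 1e-12)

  # perfectly anticorrelated rows sit at correlation distance 2
  ac <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
  colnames(ac) <- paste0("t", 1:3)
  expect_equal(max(1 - cor(t(ac))), 2)

  # constant rows get maximal distance with a warning
  cexpr <- rbind(flat = rep(2, 8), expr)
  expect_warning(hc3 <- hierarchical_cluster(cexpr, axis = "genes"),
                 "constant")

  # determinism and two-way mode
  hcb <- hierarchical_cluster(expr, axis = "both")
  expect_identical(hcb$genes$order, hc$genes$order)
  expect_equal(length(hcb$tissues$order), 8)
  expect_error(hierarchical_cluster(expr[1, , drop = FALSE], axis = "genes"),
               ">= 2")
})

test_that("correlation heatmaps match hand-computed Pearson r", {
  expr <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(4, 3, 2, 1))
  colnames(expr) <- paste0("t", 1:4)
  R <- correlation_heatmap(expr)
  expect_equal(diag(R), c(g1 = 1, g2 = 1, g3 = 1))
  expect_equal(R, t(R))
  expect_equal(R["g1", "g2"], 1)
  expect_equal(R["g1", "g3"], -1)
  # hand-computed r for a non-trivial pair
  a <- c(1, 5, 2, 8); b <- c(2, 4, 1, 9)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  R2 <- correlation_heatmap(rbind(x = a, y = b))
  expect_equal(R2["x", "y"], r_hand, tolerance = 1e-12)
  expect_error(correlation_heatmap(expr, genes = "nope"), "not in matrix")
})

test_that("database overlap computes exact intersections and Venn partitions", {
  study <- validated_interactions()
  self <- database_overlap(study, list(mirror = study))
  expect_equal(unname(self$per_set["mirror"]), 22)

  disjoint <- data.frame(ligand = c("X1", "X2"), receptor = c("Y1", "Y2"))
  none <- database_overlap(study, list(db = disjoint))
  expect_equal(unname(none$per_set["db"]), 0)

  # three constructed sets: all seven Venn regions enumerable by hand
  s1 <- data.frame(ligand = c("A", "B", "C", "D"), receptor = c("a", "b", "c", "d"))
  s2 <- data.frame(ligand = c("B", "C", "E"), receptor = c("b", "c", "e"))
  s3 <- data.frame(ligand = c("C", "D", "E", "F"), receptor = c("c", "d", "e", "f"))
  ov <- database_overlap(s1, list(two = s2, three = s3))
  expect_equal(unname(ov$per_set), c(2, 2))
  venn <- ov$venn
  expect_equal(unname(venn[["study"]]), 1)                 # A-a only
  expect_equal(unname(venn[["study&two"]]), 1)             # B-b
  expect_equal(unname(venn[["study&two&three"]]), 1)       # C-c
  expect_equal(unname(venn[["study&three"]]), 1)           # D-d
  expect_equal(unname(venn[["two&three"]]), 1)             # E-e
  expect_equal(unname(venn[["three"]]), 1)                 # F-f
  expect_equal(sum(venn), 6)

  # pair normalization: order within a pair does not matter
  flipped <- data.frame(ligand = c("a"), receptor = c("A"))
  expect_equal(unname(database_overlap(s1, list(f = flipped))$per_set), 1)
})
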