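test_that("design and parameter validation reject malformed inputs", {
  expect_error(screen_design(character()), "at least one")
  expect_error(screen_design(c("A", "A")), "unique")
  expect_error(screen_design("A", guides_per_gene = 0), ">= 1")
  expect_error(screen_design("A", true_receptors = c(B = 1)), "not in the design")
  expect_error(screen_design("A", true_receptors = c(A = 1.2)), "\\[0, 1\\]")
  expect_error(sim_params(capture_base = 0.5, capture_max = 0.2), "capture")
  expect_error(sim_params(coverage = 0), "coverage")
  expect_error(sim_params(n_rounds = 0), "n_rounds")
})

test_that("mini-library design expands to 100 gene-targeting guides", {
  pop <- build_library(mini_library_design(), sim_params())
  expect_equal(sum(pop$category == "gene"), 100)
  expect_equal(sum(pop$category != "gene"), 100)
})

test_that("degenerate dispersion settings give exact library composition", {
  des <- screen_design(paste0("G", 1:5), guides_per_gene = 4, n_controls = 8)
  set.seed(1)
  pop <- build_library(des, sim_params(abundance_cv = 0, coverage = 500))
  expect_true(all(pop$cells == 500))

  set.seed(1)
  pop1 <- build_library(des, sim_params(efficacy_mean = 1))
  expect_true(all(pop1$efficacy[pop1$category == "gene"] == 1))
  expect_true(all(pop1$efficacy[pop1$category != "gene"] == 0))

  # log-normal abundance hits the requested mean and CV approximately
  des_big <- screen_design(paste0("G", 1:500), guides_per_gene = 10)
  set.seed(2)
  popcv <- build_library(des_big, sim_params(abundance_cv = 0.5, coverage = 1000))
  expect_equal(mean(popcv$cells), 1000, tolerance = 0.05)
  expect_equal(stats::sd(popcv$cells) / mean(popcv$cells), 0.5, tolerance = 0.1)
})

test_that("one selection round matches the closed-form frequency update", {
  # one receptor (strength 1, efficacy 1) among neutral genes
  des <- screen_design(paste0("G", 1:20), guides_per_gene = 5,
                       true_receptors = c(G1 = 1))
  par <- sim_params(abundance_cv = 0, efficacy_mean = 1, coverage = 200,
                    capture_base = 0.001, capture_max = 0.9)
  set.seed(10)
  pop0 <- build_library(des, par)
  f0 <- pop0$cells / sum(pop0$cells)
  p <- ifelse(pop0$strength == 1, 0.9, 0.001)
  f1_exp <- expected_freq_after_round(f0, p)
  f2_exp <- expected_freq_after_round(f1_exp, p)
  rec <- pop0$gene_id == "G1"

  n_rep <- 200
  f1_obs <- f2_obs <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    p1 <- simulate_selection_round(pop0)
    f1_obs[r] <- sum(p1$cells[rec]) / sum(p1$cells)
    p2 <- simulate_selection_round(p1)
    f2_obs[r] <- sum(p2$cells[rec]) / sum(p2$cells)
  }
  se1 <- stats::sd(f1_obs) / sqrt(n_rep)
  se2 <- stats::sd(f2_obs) / sqrt(n_rep)
  expect_lt(abs(mean(f1_obs) - sum(f1_exp[rec])), 3 * se1)
  # two rounds equal the one-step map applied twice
  expect_lt(abs(mean(f2_obs) - sum(f2_exp[rec])), 3 * se2)
})

test_that("uniform capture preserves composition and empty capture errors", {
  des <- screen_design(paste0("G", 1:20), guides_per_gene = 5)
  par <- sim_params(abundance_cv = 0.5, coverage = 500, capture_base = 0.2,
                    capture_max = 0.9)  # no receptors: all cells at base rate
  set.seed(3)
  pop <- build_library(des, par)
  f0 <- pop$cells / sum(pop$cells)
  f1 <- replicate(100, {
    p1 <- simulate_selection_round(pop)
    p1$cells / sum(p1$cells)
  })
  dev <- rowMeans(f1) - f0
  se <- apply(f1, 1, stats::sd) / sqrt(100)
  expect_lt(mean(abs(dev) > 4 * se + 1e-12), 0.02)

  # population size is conserved by the expansion step
  set.seed(4)
  p1 <- simulate_selection_round(pop)
  expect_equal(sum(p1$cells), sum(pop$cells))

  # all-zero capture raises a diagnostic error
  tiny <- build_library(screen_design("A", guides_per_gene = 2),
                        sim_params(abundance_cv = 0, coverage = 2,
                                   capture_base = 0, capture_max = 0))
  set.seed(5)
  expect_error(simulate_selection_round(tiny), "zero cells")
})

test_that("sequencing is multinomial with exact depth", {
  des1 <- screen_design("A", guides_per_gene = 1)
  pop1 <- build_library(des1, sim_params(abundance_cv = 0, coverage = 10))
  expect_equal(unname(simulate_sequencing(pop1, 1000)), 1000)
  expect_error(simulate_sequencing(pop1, 0), "depth")

  des <- screen_design(paste0("G", 1:40), guides_per_gene = 5)
  pop <- build_library(des, sim_params(abundance_cv = 0, coverage = 100))
  set.seed(6)
  counts <- simulate_sequencing(pop, 2e6)
  expect_equal(sum(counts), 2e6)
  # uniform 200-guide population: every count within 5 binomial SDs of 1e4
  sd_bin <- sqrt(2e6 * (1 / 200) * (199 / 200))
  expect_true(all(abs(counts - 1e4) < 5 * sd_bin))
})

test_that("simulated screens are reproducible and correctly shaped", {
  des <- screen_design(paste0("G", 1:10), guides_per_gene = 3, n_controls = 6,
                       true_receptors = c(G1 = 1))
  par <- sim_params(n_rounds = 3, sequencing_depth = 1e5, seed = 11)
  s1 <- simulate_screen(des, par)
  s2 <- simulate_screen(des, par)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_equal(colnames(s1$counts$counts), c("R0", "R1", "R2", "R3"))
  expect_equal(s1$counts$samples$round, 0:3)
  expect_true(all(colSums(s1$counts$counts) == 1e5))
  expect_true(all(s1$truth$efficacy[s1$counts$library$category != "gene"] == 0))
})

test_that("a strength-1 receptor's frequency share rises every round", {
  # closed-form map: expected share is strictly increasing whenever
  # capture_max > capture_base, and the simulation tracks it
  des <- benchmark_design(n_genes = 50, n_controls = 50)
  par <- sim_params(n_rounds = 3, sequencing_depth = 1e6, seed = 12,
                    abundance_cv = 0, efficacy_mean = 1)
  pop <- local({set.seed(12); build_library(des, par)})
  p <- par$capture_base + (par$capture_max - par$capture_base) *
    pop$efficacy * pop$strength
  f <- pop$cells / sum(pop$cells)
  rec <- pop$gene_id == "G001"
  shares <- sum(f[rec])
  for (r in 1:3) {
    f <- expected_freq_after_round(f, p)
    shares <- c(shares, sum(f[rec]))
  }
  expect_true(all(diff(shares) > 0))

  scr <- simulate_screen(des, par)
  obs <- colSums(scr$counts$counts[rec, ]) / colSums(scr$counts$counts)
  expect_true(all(diff(obs) > 0))
})

test_that("a fully null screen shows no mean gene-level enrichment", {
  des <- screen_design(sprintf("G%02d", 1:30), guides_per_gene = 5,
                       n_controls = 50)
  means <- sapply(1:8, function(seed) {
    scr <- simulate_screen(des, sim_params(n_rounds = 1,
                                           sequencing_depth = 5e5,
                                           seed = seed))
    e <- guide_log_enrichment(scr$counts, "R1", "R0")
    # gene-level statistic relative to the control background
    mean(tapply(e$x[e$category == "gene"], e$gene_id[e$category == "gene"],
                mean)) - mean(e$x[e$category != "gene"])
  })
  expect_lt(abs(mean(means)), 3 * stats::sd(means) / sqrt(length(means)))
})

test_that("ground truth serializes to JSON", {
  des <- screen_design(c("A", "B"), guides_per_gene = 2, n_controls = 2,
                       true_receptors = c(A = 0.5))
  scr <- simulate_screen(des, sim_params(n_rounds = 1, sequencing_depth = 1e4))
  path <- tempfile(fileext = ".json")
  write_ground_truth(scr, path)
  gt <- jsonlite::read_json(path)
  expect_equal(gt$strength$A, 0.5)
  expect_equal(length(gt$efficacy), 6)
})
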