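Package: deorphan
Title: CRISPRa Enrichment Screen Analysis for Ligand-Receptor Deorphanization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of pooled CRISPR-activation (CRISPRa)
    enrichment screens used to pair secreted ligands with their cell-surface
    receptors. Provides a generative model of multi-round magnetic-bead
    positive selection with guide-efficacy heterogeneity, guide counting and
    enrichment from count tables or raw reads, gene-level maximum-likelihood
    effect estimation against an empirical control-guide null with
    permutation p-values, ESP-score hit calling with enrichment-trajectory
    filtering, ligand-receptor network assembly with phylogenetic-homology
    candidate expansion, expression co-clustering, and 1:1 Langmuir kinetic
    and steady-state fitting of surface plasmon resonance sensorgrams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    ape,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
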