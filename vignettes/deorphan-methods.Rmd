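---
title: "Models and methods behind deorphan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind deorphan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(deorphan)
```

`deorphan` implements the computational arm of a CRISPRa enrichment
screening platform for ligand–receptor deorphanization: a pooled library of
sgRNAs transcriptionally activates candidate cell-surface receptors, cells
binding a bead-coupled bait ligand are enriched over consecutive rounds of
magnetic positive selection, and deep sequencing of the sgRNA cassette
before and after selection identifies the receptor. This vignette describes
the generative model, the gene-level statistics, the hit-calling rules, the
downstream network/homology/clustering analyses, and the SPR fitting — with
the numerical choices and their rationale.

## The generative screen model

`simulate_screen()` produces count tables with known ground truth, which is
how the statistical machinery is validated in this package. The model is
deliberately minimal:

* **Library.** Each target gene has `guides_per_gene` sgRNAs (default 10,
  the design used throughout this platform) plus matched controls, half
  safe-targeting and half non-targeting. Initial per-guide abundance is
  log-normal with mean `coverage` cells/guide (default 1000, the complexity
  floor maintained at library banking) and CV `abundance_cv` (default 0.5,
  typical right-skew of lentivirally delivered pools).
* **Guide efficacy.** CRISPRa activation varies between guides: efficacy is
  Beta-distributed with mean 0.5 and concentration 4 (i.e. Beta(2, 2));
  controls have efficacy 0. The mean is exposed (`efficacy_mean`) so
  degenerate settings (all guides fully active) are expressible.
* **Selection.** Each cell is captured independently with probability
  `capture_base + (capture_max - capture_base) * efficacy * strength`,
  where `strength` in [0, 1] is the gene's ground-truth binding strength
  (0 for everything but true receptors). Captured cells are expanded back
  to the original population size by multinomial resampling, i.e. expansion
  preserves composition and introduces no fitness differences.
* **Sequencing.** Each sequenced sample is a multinomial draw of
  `sequencing_depth` reads (default 5e6) over current guide frequencies.
  The naive (round 0) population is sequenced before any selection and
  serves as the reference for all enrichment statistics.

The capture defaults (`capture_base = 0.05`, `capture_max = 0.15`) are the
one genuinely free calibration in the model: per-round capture efficiencies
are not measurable from sequencing data alone. They were set so that a
strength-1 receptor enriches about twofold per round — a modest first round
and a strong second round, the qualitative trajectory that consecutive MACS
selections display. Substantially higher contrast makes the first round
saturate (every receptor guide already far outside the control
distribution), which flattens the confidence score across rounds and is not
what staged selections look like; substantially lower contrast pushes
final-round effect sizes against the hit-calling cut-off. Background capture
of a few percent is typical nonspecific carryover for magnetic columns.

What the simulator does **not** model: multiple integration (MOI),
growth-rate differences between clones, PCR jackpotting, column-washing
physics, or bead avidity as a separate parameter (it is folded into
`capture_max`). Passing tests therefore demonstrate correctness of the
statistics under a clean selection model, not robustness to every artifact
of real screens; real data additionally carry overdispersion that the
control-guide null absorbs empirically.

## Gene-level statistics

`analyze_round()` compares one selected sample to the naive reference:

1. **Per-guide enrichment** `x = log2(freq_sel / freq_ref)` after adding a
   pseudocount of 0.5 to every count (finite values for dropouts; frequency
   normalization makes the statistic invariant to sequencing depth).
2. **Empirical null.** The control guides (safe-targeting plus
   non-targeting) define the null density f0 via a Gaussian KDE with
   Scott's-rule bandwidth, tabulated on 2048 grid points spanning the
   control range ± 5 bandwidths, with the log-density floored at −30 so
   far-outlying guides keep finite log-likelihoods. The floor matters: it
   bounds any single guide's contribution, which is what makes the score
   robust to one wild guide.
3. **Effect model.** A gene's maximum effect θ assumes each of its guides
   realizes a shift uniform on [0, θ] — inactive guides sit at 0, the best
   guides at θ — so the guide density is the uniform mixture
   f(x|θ) = (1/|θ|) ∫₀^{|θ|} f0(x − sgn(θ)t) dt, evaluated with 64-point
   trapezoid quadrature (quadrature error far below the grid step). The
   effect estimate is the likelihood argmax over θ ∈ [−15, 15] in steps of
   0.1 log2 units — wide enough for any physically plausible enrichment —
   with ties broken toward the smallest |θ|. The score is the
   likelihood-ratio statistic 2·[L(θ̂) − L(0)], clipped at 0, and the
   effect interval is the 2-unit profile drop {θ : L(θ) ≥ L(θ̂) − 2},
   the standard ≈95% profile interval.
4. **Permutation p-value.** Pseudo-genes of the same guide count are drawn
   with replacement from the pool of **all** gene-targeting guide
   enrichments (conservative in real screens, where most genes are null,
   and exactly calibrated in the fully null simulator), the score is
   recomputed for each, and p = (1 + #{perm ≥ obs}) / (N + 1) with
   N = 10,000 by default. Genes with the same guide count share one
   permutation distribution — this changes nothing statistically and makes
   the default N cheap. p can never fall below 1/(N+1).

## Hit calling

The combined ranking statistic is `esp = (effect + score) / p`, with p
floored at 1/(N+1) so the ratio is always defined. Hits must pass the
first-pass filter — effect > 2, score > 2, p < 0.05, all strict — be
annotated inside the membrane or secreted proteome, and not sit on the
contaminant blacklist (shipped empty: recurrent contaminants are curated
per platform, not universal). Finally, the ESP trajectory across rounds
must be *positive*: nondecreasing up to a 10% relative dip per step and
ending above its first-round value. The tolerance acknowledges sampling
noise between rounds; the strict final-above-first requirement is what
eliminates the characteristic false positive that spikes early and decays.
With a single round of data no trajectory exists and
`first_pass_filter()` + `rank_hits()` is the supported path.

## Network, homology, clustering

`build_network()` does exact set arithmetic over unordered ligand–receptor
pairs; the packaged `validated_interactions()` fixture encodes the 22 validated
interactions (18 single-pass/TM1 from 8 ligand screens, 4 multi-pass/TM2+
from 4), and `database_overlap()` computes exact Venn partitions against
external interaction databases after symbol normalization.

Phylogenetic homology analysis (`pha_candidates()`) proposes family members
of a validated receptor as additional candidates. Distances are
1 − identity from pairwise Needleman–Wunsch global alignment (BLOSUM62,
gap open 10, extend 1 — conventional protein defaults), rather than a full
multiple sequence alignment: pairwise distances are deterministic,
dependency-free, and adequate for subfamily grouping, which is all the
candidate expansion needs. The distance threshold δ defaults to 0.6 —
within-subfamily pairs of the receptor families this platform works with
(e.g. receptor phosphatase ectodomains, KIR-family domains) fall well
inside it while between-subfamily pairs do not — and is exposed because it
is a judgement call. Trees come from neighbor joining (`ape::nj`), which is
exact on additive matrices; negative branch lengths arising on non-additive
input are clamped to zero.

Expression co-clustering uses Ward linkage (`ward.D2`) on correlation
distance (1 − Pearson r), the standard recipe for tissue-expression
heatmaps; rows without variance have undefined correlation and are placed
at the maximal distance 2 with a warning rather than an error, so one flat
housekeeping profile cannot abort a clustering.

## SPR fitting

The 1:1 Langmuir model has a closed-form solution — association
R(t) = Req·(1 − e^{−(kon·C + koff)t}) with Req = Rmax·C/(C + KD), and
exponential dissociation — so `simulate_sensorgram()` and `fit_kinetic()`
use it directly instead of integrating the ODE. The kinetic fit is global
across all concentration traces (shared kon, koff, Rmax), on log-parameters
(positivity for free), by Levenberg–Marquardt from 8 log-spaced kon starts
with koff seeded from a log-linear fit of the dissociation tails; the loss
surface has local minima when associations are short, and the multi-start
reliably escapes them. Dissociation-only data identify koff but not kon,
and the fit says so (`kon_identifiable = FALSE`) instead of returning a
spurious number. `fit_steady_state()` fits the binding isotherm
Req(C) = Rmax·C/(C + KD) and flags the fit as underdetermined when the
fitted KD exceeds the highest tested concentration, the classic failure of
a titration that never approaches saturation. Traces are assumed
pre-referenced (blank-cell subtraction done upstream); bulk-shift terms,
mass transport, and multi-state models are out of scope.

## Problem sizes used in the checks

The packaged validation suite exercises the benchmark scenario at the scale
of the original workflow validation — 200 targets × 10 guides plus 200
controls, two selection rounds, 100 replicate screens — and null
calibration on 1000-target screens with N = 500 permutations (p-value
resolution 1/501, ample for a 0.05 threshold). The acceptance script runs
the same computations at 25 benchmark replicates. These sizes were chosen
so the whole validation is a coffee-break run on a laptop while keeping
binomial counting error on the reported rates a few percent.

## Worked example

```{r example, eval = FALSE}
genes <- sprintf("G%03d", 1:200)
design <- screen_design(genes, guides_per_gene = 10, n_controls = 200,
                        true_receptors = c(G001 = 1))
screen <- simulate_screen(design, sim_params(n_rounds = 2, seed = 42))

cfg <- analysis_config(n_perm = 1000, seed = 42)
rounds <- list(analyze_round(screen$counts, "R1", "R0", cfg),
               analyze_round(screen$counts, "R2", "R0", cfg))
annotation <- setNames(rep("TM1-membrane", length(genes)), genes)
hits <- call_hits(rounds, annotation)
hits[hits$called, c("rank", "gene", "effect", "score", "p_value", "esp")]
```

## Known limitations

* The gene-level effect/score/p machinery is a normative reconstruction of
  the maximum-likelihood screen-analysis approach it follows; exact
  numerical agreement with any particular implementation of that approach
  is not a goal, and units of the score are likelihood-ratio units.
* The ESP statistic divides by p, so for genes at the permutation floor the
  ranking is driven by effect + score alone; increasing `n_perm` sharpens
  the floor.
* Saturated screens (a receptor dominating the pool by round 1) compress
  the score across rounds; trajectory classification is most informative
  when per-round enrichment is staged, which the simulator defaults
  reproduce.
* PHA distances are pairwise, not MSA-based; for deep families with
  heavy indels an MSA-based tree may group differently.
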