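---
title: "metpleio: models, generator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metpleio: models, generator, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metpleio)
```

## Scope and model

`metpleio` interprets pleiotropic GWAS signals on a panel of biochemically
related metabolites through their reaction network. The central objects are:

* a **lead variant**: the minimum-p representative of an LD clump, merged
  across traits within 0.1 cM;
* a **significant metabolite pair** for a variant: suggestive association
  (p < 1e-4) in both metabolites, genome-wide significance (p < 5e-8) in at
  least one, and a pairwise genetic correlation whose local false sign rate
  is below 0.005;
* a **discordant** variant: one whose effect-sign product on a significant
  pair opposes the sign of that pair's global genetic correlation;
* the **between region** of a pair: the shortest path connecting the two
  metabolites in the reaction graph, plus all simple paths at most `slack`
  (default 1) steps longer. Genes act *between* a pair if they encode an
  enzyme on such a path or a transporter whose cargo lies on it (endpoints
  included). All edges are traversed bidirectionally: even one-way reactions
  couple product and reactant levels in both directions (mass-action
  re-equilibration), so collider-containing routes are admissible and no
  directionality filter is applied.

Upstream/downstream attribution for non-between genes uses the canonical
substrate-to-product orientation: genes attaching to ancestors of the path
region are upstream (this is where entry-node regulators land), to strict
descendants downstream, otherwise outside. Because ancestor/descendant sets
of the region are themselves symmetric in the pair, the full label is
symmetric under swapping the two metabolites.

## Thresholds and parameters

| parameter | default | meaning |
|---|---|---|
| `clump_p` | 1e-4 | index and assigned-variant p threshold for clumping |
| `clump_r2` | 0.01 | r² above which a variant joins a clump |
| `clump_window_bp` | 1e6 | clumping window |
| `merge_cm` | 0.1 | cross-trait merge radius (cM) |
| `gw_p` / `suggestive_p` | 5e-8 / 1e-4 | significance tiers |
| `lfsr_cut` | 0.005 | pair filter on the local false sign rate |
| `flank_bp` | 1e5 | standard gene window and region flank |
| `enzyme_flank_bp` | 5e5 | window for biologically relevant enzymes |
| `fallback_flank_bp` | 2e5 | retry window when nothing known is near |
| `slack` | 1 | admissible extra path length for "between" |

If no genetic map is supplied, positions map at 1 cM/Mb; the merge radius
then equals 100 kb on the synthetic genome.

## The lfsr implementation

The pair filter re-implements normal-mixture adaptive shrinkage rather than
calling an external package, so that the posterior sign probabilities can be
validated against direct numeric integration (see
`test-concordance.R`). The prior is `pi0 * delta0 + sum_k pik * N(0,
sigma_k^2)` with the sigma grid ascending in sqrt(2) multiplicative steps
from `min(se)/10` to `2 * sqrt(max(est^2 - se^2, 0))`, fitted by EM with a
penalty weight of 10 on the null component (the conventional default, which
biases toward conservatism). lfsr values include the point mass in both
tails, so a zero estimate has lfsr >= 0.5 and lfsr >= lfdr always. The EM
stops when the penalized log-likelihood moves by < 1e-8; non-convergence
within 50,000 iterations is an error, never a silent result. Half-uniform
mixture components are out of scope. All pairs of a study are fitted
jointly.

## Exact kernels

* **Poisson rate test**: inference conditional on the total count,
  `x1 ~ Binomial(x1 + x2, L1/(L1 + L2))` under the null. Two-sided p by the
  probability-mass rule (sum of outcomes no more probable than observed,
  with the customary 1 + 1e-7 tie guard); CI by mapping the Clopper–Pearson
  interval on the binomial proportion through `RR = q/(1-q) * L2/L1`.
* **Fisher exact**: probability-mass p over the conditional distribution;
  odds ratio as the conditional MLE solving `E_theta[A] = a` under Fisher's
  noncentral hypergeometric (solved by `uniroot` in log theta to 1e-12 —
  note `stats::fisher.test` carries a looser optimizer tolerance, which the
  tests account for); CI by inverting one-sided tails at (1-conf)/2.
  Degenerate margins give an undefined OR with p = 1.
* **Wilson interval** and the two-group **Fligner–Killeen** statistic follow
  their textbook forms (midranks for ties; chi-squared with 1 df for two
  groups).

## Local genetic correlation aggregation

Per-block covariances and heritabilities are summed over the blocks
overlapping the pathway's ±100 kb gene-region union (a block counts wholly
if it intersects at all; no fractional weighting), and
`rg_l = sum(cov) / sqrt(sum(h2_a) * sum(h2_b))`. The variance of each sum is
the sum of per-block variances, and `var(rg_l)` follows by the delta method
treating the three sums as independent — the consumed per-block tables carry
no cross-covariances, so this is a documented approximation that slightly
misstates the SE when covariance and heritability errors correlate.
Non-positive heritability sums are an error, never clipped. A nonparametric
alternative compares per-block covariance spread between a pathway and a
baseline with the Fligner–Killeen test.

## Mendelian randomization

Instruments are merged leads genome-wide significant in the exposure (at
least 3; no Steiger filtering — the instrument-selection rule is this
package's choice). IVW and MR-Egger are computed as weighted regressions
with weights `1/se_outcome^2` and classical (unscaled) standard errors.
Selection follows the heterogeneity ladder: if the IVW Q statistic sits
within its chi-squared 95% critical value, fixed-effect IVW is reported;
otherwise, if Q − Q' exceeds the 1-df critical value, the Egger branch is
taken; within the chosen branch the SE is inflated by `sqrt(Q/df)`
(multiplicative random effects) when the branch's own heterogeneity exceeds
its critical value.

## What the generator emulates — and what it does not

The synthetic world mirrors the study design the pipeline targets: 16
metabolites in four biochemical groups (glycolysis 4, BCAA 3, other amino
acids 6, ketone bodies 3) on a hand-curated reaction graph whose edges may
summarize multiple reaction steps (glycolysis, alanine/glycine
transamination into pyruvate, glutaminolysis, aromatic amino acid
degradation into acetoacetate, BCAA catabolism into the TCA cycle, ketone
interconversion, and a gluconeogenic lactate→glucose edge that closes the
Cori cycle and exercises cycle handling).

Mechanisms are planted as activity effects `a` propagated with geometric
decay `d^k` per reaction step:

* **enzyme** on edge (u, v): substrate side `-a d^k`, product side
  `+a d^k`, sides determined by deleting the edge (on cycles, by the shorter
  path to either endpoint; exact ties get zero effect);
* **transporter** with cargo m: plasma m gets `-a`, metabolites strictly
  downstream of m's intracellular consumption `+a d^k`;
* **regulator (TF)** at an entry node and **polygenic background** from a
  random entry node: same-signed `a d^k` everywhere.

Two decay constants are used: `d_local = 0.5` for enzyme/transporter
propagation and `d_global = 0.85` for regulator/background mechanisms. The
slower global decay is what makes the polygenic background correlations
uniformly positive (median true rg ≈ 0.6 at the defaults), matching the
empirically observed strongly positive genome-wide correlations among such
metabolites; with a single d = 0.5 the planted between-edge enzymes would
dominate the cross-products and flip many true correlations negative, which
is not the world this pipeline targets. Default counts are 50/30/50/70
enzyme/transporter/TF/background causal variants (≈200, in linkage
equilibrium so the true `rg` stays closed-form) plus 2000 decoys, of which
two per causal site are LD copies at r² 0.8 and 0.3 with distance scaled by
(1 − r²) — high-r² pairs sit close, as in real genomes — to exercise
clumping. Summary statistics use `se = s0/sqrt(n)` with n = 1e5 and
`beta_hat = beta_true + N(0, se^2)`; pair-rg estimates add N(0, 0.05²)
noise; per-block covariances and heritabilities add N(0, (2e-3)²).

Pathway genes are placed with a minimum 4 Mb spacing so distinct pathway
gene sets occupy distinct LD blocks (real metabolic genes are scattered
genome-wide); decoys are uniform. The genome is 4 × 60 Mb with 2 Mb blocks.

A green planted-truth test therefore establishes that the pipeline recovers
mechanism-driven sign structure under standard GWAS noise with block-wise LD
of known form. It does not establish robustness to realistic LD panels,
assortative mating or population structure, winner's-curse effect-size
inflation, missing or misassigned genes in the curated network, or
non-additive trait architectures — none of which the generator emulates.

Trait QC follows the raw-scale outlier rule: a sample is dropped when a
metabolite exceeds median + 20·IQR or falls below median/10, then levels are
log-transformed. The upper rule's published phrasing ("greater than 20-fold
the interquartile range") is ambiguous about its reference point; both
readings are implemented (`qc_upper_rule = "median_plus_20iqr"` default,
`"20iqr"` alternative). The default was chosen because the alternative
excludes every sample whenever 20·IQR falls below the median, which cannot
be the intended behavior for tightly distributed positive metabolites; the
below-median rule is read on the raw scale since a strictly positive level
cannot be "median − 10·IQR" in general.

## Numerical and design choices

* Greedy tie-breaks in clumping and merging are ascending p, then (chrom,
  position), making both stages deterministic and input-order invariant; the
  published pipelines do not state their tie-breaks.
* "Biological relevance" of a distal enzyme is a non-empty intersection of
  the gene's relevant metabolites with the variant's suggestive set; within
  a gene-type tier, the largest such intersection wins, then smaller
  distance, then gene id. This determinizes a manual curation step whose
  decisive output is the gene *type*.
* For the between-versus-not enrichment table, a variant's "defining pairs"
  are its discordant pairs when discordant and all its significant pairs
  when concordant; the choice is switchable because the published analysis
  does not spell it out.
* Any declared transporter cargo counts as "primarily transported".
* The sign of rg for classification is taken from the lfsr-passing point
  estimate, not a shrunken posterior mean.
* Effect-matrix normalization uses the (r − 0.5)/n rank offset (Blom
  available by option); rows are sign-aligned after column standardization,
  so exact column moments hold before alignment.
* The inverse-normal rank offset, all windows, the path slack, and every
  threshold are config-exposed (`met_config()`), with the defaults above.

## Known limitations

* One acceptance subcheck is deliberately red: the required empirical
  Wilson coverage band [93%, 97%] at n = 20, p = 0.3 is infeasible for the
  uncorrected score interval, whose exact coverage there is 0.9752 (the
  k = 2 and k = 10 intervals cover 0.3 by margins of 1e-3 and 7e-4). The
  implementation matches the score-quadratic roots to 1e-8; the band, not
  the code, is the problem.
* The delta-method SE for pathway-level rg ignores cross-covariances among
  the three sums (not carried by the input tables).
* The generator's LD model is deliberately minimal (tiered copies of causal
  sites); clumping correctness against richer LD is validated only via the
  brute-force greedy oracles.
* MR shares the merged leads across all trait pairs; no per-pair instrument
  pruning is attempted.
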