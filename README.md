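# metpleio

Pathway-aware analysis of pleiotropy in metabolite GWAS.

## The problem

GWAS of panels of biochemically related plasma metabolites (amino acids,
glycolysis intermediates, ketone bodies) show pervasive pleiotropy: most lead
variants move several metabolites at once, and most metabolite pairs carry a
strongly positive genome-wide genetic correlation. Yet the variants that sit
directly *between* two metabolites in the reaction network — enzymes
catalyzing a step on the biochemical path connecting them, or transporters
clearing one of the pair from plasma — tend to push the two metabolites in
*opposite* directions, against the polygenic background. Identifying these
"discordant" variants, and showing that they concentrate on between-pair
biology, turns an abstract genetic-correlation estimate into a mechanistic
statement about where in the pathway a variant acts.

`metpleio` implements that analysis for anyone with per-metabolite GWAS
summary statistics, a gene annotation table, and a curated reaction network:

* **hits** — per-trait greedy LD clumping (p < 1e-4, r² > 0.01, 1 Mb) and
  cross-metabolite merging of hits within 0.1 cM, keeping the minimum-p SNP.
* **annotate** — one gene per lead by a deterministic priority rule
  (pathway-relevant enzyme > transporter > TF > general function), with a
  100 kb window, 500 kb for biologically relevant enzymes, 200 kb fallback.
* **pathway_graph** — shortest biochemical paths (plus near-shortest
  alternatives), "between / upstream / downstream / outside" labels for every
  (gene, metabolite pair), and flanked gene-region unions.
* **concordance** — an adaptive-shrinkage local false sign rate
  (`lfsr = min(P(effect <= 0 | data), P(effect >= 0 | data))` under a fitted
  point-mass + zero-centered normal mixture prior) filters the pairwise
  genetic correlations; a variant is *discordant* when
  `sign(beta_1) * sign(beta_2) != sign(rg)` for a significant pair
  (p < 1e-4 in both, p < 5e-8 in one, pair lfsr < 0.005).
* **enrichstats** — exact Poisson rate-ratio test (conditional binomial),
  Fisher's exact test with conditional-MLE odds ratio, Wilson score
  intervals, Fligner–Killeen variance test.
* **localrg** — pathway-level local genetic correlation
  `rg_l = sum(cov) / sqrt(sum(h2_a) * sum(h2_b))` over the LD blocks
  overlapping a pathway's ±100 kb gene regions, with a delta-method SE.
* **mr** — pairwise Mendelian randomization (IVW and MR-Egger, fixed and
  random effects) with Rücker heterogeneity-driven model selection.
* **effects_matrix** — rank-based inverse-normal standardization of the
  lead × metabolite z-score matrix with positive-median row alignment.
* **synthetic_data** — a seeded generator: a curated 16-metabolite reaction
  network (4 glycolysis, 3 BCAA, 6 other amino acid, 3 ketone-body nodes),
  planted enzyme/transporter/TF/background variants with closed-form true
  effects and genetic correlations, decoy variants with fixed-r² LD copies,
  and noisy summary-stat / pair-rg / LD-block emitters with known truth.

## Worked example

```r
library(metpleio)

st  <- simulate_study(met_config(), seed = 1)   # synthetic 16-metabolite study
res <- run_pipeline(st)                          # clump + merge + annotate + classify

nrow(res$leads)
#> [1] 147
table(res$calls$calls$class)
#> concordant discordant    neither
#>         82         63          2

tabs <- build_enrichment_tables(res$calls, res$annotations, st$truth$labels)
tabs$gene_type
#>            enz_or_trans other
#> discordant           57     6
#> concordant            2    80
fisher_exact(57, 6, 2, 80)
#> fisher_exact: statistic = 337.9, 95% CI [66.64, 3511], p = 9.44e-31
```

147 merged lead variants; 63 are discordant for at least one significant
metabolite pair, and discordant variants are overwhelmingly annotated with
enzyme or transporter genes (conditional-MLE OR ≈ 338 on this planted
architecture), which is exactly the planted mechanism: enzyme and transporter
perturbations split the network into opposite-signed sides, while TF and
polygenic background effects are same-signed everywhere.

The exact kernels reproduce published-scale numbers directly; e.g. 68 hits
in 24.29 Mb of enzyme gene regions against 213 hits in 1950 Mb:

```r
poisson_rate_test(68, 24.29, 213, 1950)
#> poisson_rate: statistic = 25.63, 95% CI [19.21, 33.82], p = 1.85e-65
```

a ~26-fold enrichment with a 95% CI of roughly [20, 33].

## Command line

```sh
Rscript inst/cli/metpleio.R simulate --seed 3 --out study/
Rscript inst/cli/metpleio.R clump    --in study/ --out study/leads.tsv
Rscript inst/cli/metpleio.R classify --in study/ --out study/calls.tsv
# also: merge | annotate | enrich | localrg | mr | report
```

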