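Package: metpleio
Title: Pathway-Aware Analysis of Pleiotropy in Metabolite GWAS
Version: 0.1.0
Authors@R:
    person("Metpleio", "Developers", email = "metpleio@example.org",
           role = c("aut", "cre"))
Description: Tools for interpreting pleiotropic GWAS signals on panels of
    biochemically related metabolites. Implements per-trait LD clumping and
    cross-trait lead merging, rule-based variant-to-gene annotation with
    gene-type priorities, metabolic-network "between" logic for metabolite
    pairs, adaptive-shrinkage local false sign rates for pairwise genetic
    correlations, discordant/concordant variant classification, exact
    enrichment statistics (Poisson rate test, Fisher exact test with
    conditional-MLE odds ratio, Wilson intervals, Fligner-Killeen),
    aggregation of per-LD-block local heritability and covariance into
    pathway-level genetic correlations, Mendelian randomization with Rucker
    model selection, and a seeded synthetic metabolic-network / genetic
    architecture generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
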