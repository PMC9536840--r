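# Aggregation of per-LD-block local heritabilities and genetic covariance
# over pathway gene regions into a pathway-level genetic correlation.

#' LD blocks overlapping a pathway's flanked gene regions
#'
#' @param blocks block table (`chrom`, `start_bp`, `end_bp`, `block_id`).
#' @param gene_ids pathway genes.
#' @param genes a `gene_table`.
#' @param flank_bp flank around gene boundaries (default 1e5).
#' @param chrom_lengths named chromosome lengths (for end truncation).
#' @param complement if TRUE, return the blocks NOT overlapping the region
#'   ("all regions outside pathway genes").
#' @return the qualifying subset of `blocks`.
#' @export
blocks_for_pathway <- function(blocks, gene_ids, genes, flank_bp = 1e5,
                               chrom_lengths, complement = FALSE) {
  region <- region_union(gene_ids, genes, flank_bp, chrom_lengths)$intervals
  gr_b <- GenomicRanges::GRanges(blocks$chrom,
                                 IRanges::IRanges(blocks$start_bp,
                                                  blocks$end_bp))
  gr_r <- GenomicRanges::GRanges(region$chrom,
                                 IRanges::IRanges(region$start_bp,
                                                  region$end_bp))
  hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(gr_b, gr_r)))
  sel <- seq_len(nrow(blocks)) %in% hit
  if (complement) sel <- !sel
  blocks[sel, ]
}

#' Aggregate block statistics into a pathway-level genetic correlation
#'
#' Sums covariances and heritabilities over the block subset:
#' rg_l = sum(cov) / sqrt(sum(h2_a) * sum(h2_b)). The variance of each sum is
#' the sum of per-block variances, and var(rg_l) follows by the delta method
#' treating the three sums as independent:
#' var(rg_l) = rg_l^2 * (var(Scov)/Scov^2 + var(Sa)/(4 Sa^2) +
#' var(Sb)/(4 Sb^2)). Significance is the two-sided normal tail of
#' rg_l / se.
#'
#' @param block_subset `block_stats` rows (see [emit_block_stats()]).
#' @param pathway_id label for the result.
#' @return list: `pathway_id`, `n_blocks`, `rg_l`, `se`, `p`, `sum_cov`,
#'   `sum_h2_a`, `sum_h2_b`, `var_sum_cov`, `var_sum_h2_a`, `var_sum_h2_b`.
#' @export
aggregate_local_rg <- function(block_subset, pathway_id = "pathway") {
  if (!nrow(block_subset)) stop("aggregate_local_rg: empty block subset")
  s_cov <- sum(block_subset$cov_ab)
  s_a <- sum(block_subset$h2_a)
  s_b <- sum(block_subset$h2_b)
  if (s_a <= 0 || s_b <= 0) {
    stop("aggregate_local_rg: non-positive heritability sum; local genetic ",
         "correlation undefined")
  }
  v_cov <- sum(block_subset$var_cov)
  v_a <- sum(block_subset$var_h2_a)
  v_b <- sum(block_subset$var_h2_b)
  rg_l <- s_cov / sqrt(s_a * s_b)
  var_rg <- rg_l^2 * (v_cov / s_cov^2 + v_a / (4 * s_a^2) + v_b / (4 * s_b^2))
  se <- sqrt(var_rg)
  list(pathway_id = pathway_id, n_blocks = nrow(block_subset), rg_l = rg_l,
       se = se, p = rg_wald_p(rg_l, se), sum_cov = s_cov, sum_h2_a = s_a,
       sum_h2_b = s_b, var_sum_cov = v_cov, var_sum_h2_a = v_a,
       var_sum_h2_b = v_b)
}

#' Two-sided normal p-value for an estimate and its standard error
#'
#' @param estimate,se estimate and standard error (se >= 0; a zero SE gives
#'   the degenerate p of 0 or 1).
#' @return p = 2 * pnorm(-|estimate| / se).
#' @export
rg_wald_p <- function(estimate, se) {
  stopifnot(se >= 0)
  if (se == 0) return(as.numeric(estimate == 0))
  2 * stats::pnorm(-abs(estimate) / se)
}

#' Nonparametric pathway contrast of per-block genetic covariances
#'
#' Compares the spread of per-block covariance scores of a pathway against a
#' baseline block set with the Fligner-Killeen variance test; this jointly
#' captures enrichment of heritability and covariance without being driven
#' by outlier blocks.
#'
#' @param block_subset,baseline_subset `block_stats` rows.
#' @return [fligner_test()] result.
#' @export
pathway_contrast_fligner <- function(block_subset, baseline_subset) {
  fligner_test(block_subset$cov_ab, baseline_subset$cov_ab)
}
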