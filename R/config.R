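#' Analysis configuration with the pipeline's default thresholds
#'
#' Bundles every tunable threshold of the pipeline together with the
#' synthetic-generator settings. Threshold defaults follow the conventions of
#' large-scale metabolite GWAS processing: plink-style clumping at
#' p < 1e-4 / r2 > 0.01 / 1 Mb, cross-trait merging of hits within 0.1 cM,
#' genome-wide significance 5e-8, suggestive significance 1e-4, a local false
#' sign rate cut of 0.005 for pairwise genetic correlations, and
#' variant-to-gene windows of 100 kb (standard), 500 kb (pathway-relevant
#' enzymes), and 200 kb (fallback).
#'
#' @param clump_p p-value threshold for clump index and assigned variants.
#' @param gw_p genome-wide significance threshold.
#' @param suggestive_p suggestive association threshold.
#' @param lfsr_cut local false sign rate cut for pair correlations.
#' @param merge_cm cross-trait greedy merge radius in centimorgans.
#' @param clump_r2 LD r-squared above which variants join a clump.
#' @param clump_window_bp clumping window in base pairs.
#' @param flank_bp standard gene assignment window (bp).
#' @param enzyme_flank_bp extended window for pathway-relevant enzymes (bp).
#' @param fallback_flank_bp fallback window when nothing lies within
#'   `flank_bp` (bp).
#' @param slack admissible extra path length over the shortest biochemical
#'   path when computing "between" regions.
#' @param seed integer seed recorded with the configuration.
#' @param ... synthetic-generator settings overriding the defaults in
#'   `met_sim_defaults()`.
#' @return A list of class `met_config`.
#' @export
met_config <- function(clump_p = 1e-4,
                       gw_p = 5e-8,
                       suggestive_p = 1e-4,
                       lfsr_cut = 0.005,
                       merge_cm = 0.1,
                       clump_r2 = 0.01,
                       clump_window_bp = 1e6,
                       flank_bp = 1e5,
                       enzyme_flank_bp = 5e5,
                       fallback_flank_bp = 2e5,
                       slack = 1,
                       seed = 1L,
                       ...) {
  cfg <- c(
    list(
      clump_p = clump_p, gw_p = gw_p, suggestive_p = suggestive_p,
      lfsr_cut = lfsr_cut, merge_cm = merge_cm, clump_r2 = clump_r2,
      clump_window_bp = clump_window_bp, flank_bp = flank_bp,
      enzyme_flank_bp = enzyme_flank_bp, fallback_flank_bp = fallback_flank_bp,
      slack = slack, seed = as.integer(seed)
    ),
    met_sim_defaults()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  thr <- c(
    "clump_p", "gw_p", "suggestive_p", "lfsr_cut", "merge_cm", "clump_r2",
    "clump_window_bp", "flank_bp", "enzyme_flank_bp", "fallback_flank_bp"
  )
  bad <- thr[!vapply(cfg[thr], function(x) is.numeric(x) && x > 0, logical(1))]
  if (length(bad)) {
    stop("configuration thresholds must be positive: ",
         paste(bad, collapse = ", "))
  }
  structure(cfg, class = "met_config")
}

#' Default settings of the synthetic-data generator
#'
#' The defaults describe the emulated study: 16 metabolites in four
#' biochemical groups on a curated reaction graph, roughly 200 planted causal
#' variants (enzyme, transporter, transcription-factor and polygenic
#' background mechanisms), 2000 decoy variants of which two LD copies per
#' causal site exercise clumping, and a GWAS effective sample size of 1e5.
#'
#' @return Named list of generator settings.
#' @export
met_sim_defaults <- function() {
  list(
    topology = "metabolism16",
    chain_nodes = c("A", "B", "C"),
    chrom_lengths = c(chr1 = 6e7, chr2 = 6e7, chr3 = 6e7, chr4 = 6e7),
    n_decoy_genes = 300L,
    gene_length = 2e4,
    min_pathway_gene_spacing = 4e6,
    block_size = 2e6,
    n_enzyme = 50L,
    n_transporter = 30L,
    n_tf = 50L,
    n_background = 70L,
    n_decoy = 2000L,
    ld_r2_tiers = c(0.8, 0.3),
    a_enzyme = c(0.04, 0.15),
    a_transporter = c(0.04, 0.15),
    a_tf = c(0.04, 0.12),
    a_background = c(0.005, 0.03),
    d_local = 0.5,
    d_global = 0.85,
    n_eff = 1e5,
    s0 = 1,
    rg_noise_sd = 0.05,
    block_noise_sd = 2e-3,
    focal_pair = c("alanine", "glutamine"),
    qc_upper_rule = "median_plus_20iqr"
  )
}

#' Hash of a configuration, for run logging
#'
#' @param config a `met_config`.
#' @return md5 hex string of the canonicalized configuration.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(config)[order(names(config))]), f)
  unname(tools::md5sum(f))
}

#' Structured log line to standard error
#'
#' @param ... message parts, pasted together.
#' @keywords internal
met_log <- function(...) {
  message(sprintf("[metpleio %s] %s", format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}
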