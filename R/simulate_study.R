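#' Simulate a complete synthetic metabolite GWAS study
#'
#' Generates the network and gene placements, plants a genetic architecture,
#' and emits every table the downstream pipeline consumes: summary
#' statistics, the LD pair table, pairwise genetic-correlation estimates,
#' genome-tiling LD blocks, and per-block statistics for the focal pair.
#' All randomness derives from `seed` via fixed small offsets, so identical
#' configuration + seed reproduce identical outputs.
#'
#' @param config a [met_config()].
#' @param seed integer seed (< 2^31 - 5).
#' @param labels optional precomputed [between_labels()] (shared across
#'   replicate calls for speed).
#' @return list: `network`, `genes`, `truth`, `sumstats`, `ld`, `pair_rg`,
#'   `blocks`, `block_stats`, `config`.
#' @export
simulate_study <- function(config = met_config(), seed = config$seed,
                           labels = NULL) {
  seed <- as.integer(seed)
  net <- make_network(config, seed)
  truth <- simulate_architecture(net$network, net$genes, config, seed + 1L,
                                 labels = labels)
  ss <- emit_sumstats(truth, n = config$n_eff, seed = seed + 2L,
                      s0 = config$s0)
  pr <- emit_pair_rg(truth, noise_sd = config$rg_noise_sd, seed = seed + 3L)
  blocks <- make_blocks(config$chrom_lengths, config$block_size)
  bs <- emit_block_stats(truth, blocks, pair = config$focal_pair,
                         noise_sd = config$block_noise_sd, seed = seed + 4L)
  list(network = net$network, genes = net$genes, truth = truth,
       sumstats = ss, ld = truth_ld(truth), pair_rg = pr, blocks = blocks,
       block_stats = bs, config = config)
}

#' Run clumping, merging, annotation and classification on a study
#'
#' Convenience wrapper chaining [clump()] per metabolite, [merge_leads()],
#' [annotate_leads()], [pair_lfsr()] and [classify_leads()].
#'
#' @param study output of [simulate_study()] (or a list with the same
#'   `sumstats`, `ld`, `genes`, `pair_rg`, `config` fields).
#' @return list: `leads`, `annotations`, `pair_rg` (with lfsr), `calls`.
#' @export
run_pipeline <- function(study) {
  cfg <- study$config
  mets <- metabolites(study$sumstats)
  idx <- lapply(mets, function(m) {
    clump(study$sumstats, study$ld, m, cfg$clump_p, cfg$clump_r2,
          cfg$clump_window_bp)
  })
  leads <- merge_leads(idx, study$sumstats, cfg$merge_cm, cfg$gw_p,
                       cfg$suggestive_p)
  ann <- annotate_leads(leads, study$genes, cfg)
  pr <- pair_lfsr(study$pair_rg)
  calls <- classify_leads(leads, pr, cfg)
  list(leads = leads, annotations = ann, pair_rg = pr, calls = calls)
}
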