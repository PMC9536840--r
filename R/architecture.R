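# Planted genetic architectures with known ground truth. Causal sites are in
# linkage equilibrium; LD enters only through decoy copies of causal sites at
# fixed r2 tiers inside the clumping window, so the true pairwise genetic
# correlation stays closed-form:
#   rg(m1, m2) = sum_j b_j1 b_j2 / sqrt(sum_j b_j1^2 * sum_j b_j2^2).

.runif_signed <- function(n, range) {
  stats::runif(n, range[1], range[2]) * sample(c(-1, 1), n, replace = TRUE)
}

#' Simulate a planted genetic architecture on a metabolic network
#'
#' Plants `n_enzyme` + `n_transporter` + `n_tf` + `n_background` causal
#' variants with mechanism-specific true effect vectors from
#' [propagate_effect()], positions within `flank_bp` of their assigned gene
#' (background variants near decoy genes or intergenic), plus `n_decoy` null
#' variants of which two per causal site are LD copies at the configured r2
#' tiers. Enzyme/transporter perturbations decay at `d_local` per reaction
#' step; regulator and background mechanisms, which model diffuse systemic
#' regulation, decay at the slower `d_global`, which is what makes the
#' polygenic background correlations positive.
#'
#' @param network a `met_network`.
#' @param genes the matching `gene_table` from [make_network()].
#' @param config a [met_config()].
#' @param seed integer seed.
#' @param labels optional precomputed [between_labels()] table (they depend
#'   only on the topology, so they can be shared across replicates).
#' @return A `met_truth` list: `variants` (one row per variant: id, position,
#'   gene, mechanism, activity effect, causal flag, LD parent and r2),
#'   `beta` (variants x metabolites true effect matrix), `rg` (true pairwise
#'   correlation matrix, NA where undefined), `labels`, `d_local`,
#'   `d_global`, `metabolites`.
#' @export
simulate_architecture <- function(network, genes, config = met_config(),
                                  seed = config$seed, labels = NULL) {
  set.seed(seed)
  mets <- network$nodes$id
  ng <- network_genes(network)
  chrom_lengths <- unlist(config$chrom_lengths)

  pick_genes <- function(type, n) {
    pool <- ng$gene_id[ng$gene_type == type]
    sample(pool, n, replace = TRUE)
  }
  mech_n <- c(enzyme = config$n_enzyme, transporter = config$n_transporter,
              tf = config$n_tf, background = config$n_background)
  rows <- list()
  for (mech in names(mech_n)) {
    n <- mech_n[[mech]]
    if (n == 0) next
    if (mech == "background") {
      gid <- rep(NA_character_, n)
      entry <- sample(mets, n, replace = TRUE)
    } else {
      gid <- pick_genes(mech, n)
      entry <- rep(NA_character_, n)
    }
    a <- .runif_signed(n, config[[paste0("a_", mech)]])
    rows[[mech]] <- data.table::data.table(
      gene_id = gid, mechanism = mech, a = a, entry = entry
    )
  }
  vars <- data.table::rbindlist(rows)
  vars[, variant_id := sprintf("v%04d", .I)]
  vars[, is_causal := TRUE]

  # positions: causal variants within flank_bp of their gene; background
  # variants mostly near decoy genes (so annotation sees general/unknown),
  # the rest intergenic
  decoy_genes <- genes[grepl("^DECOY", genes$gene_id), ]
  pos <- integer(nrow(vars)); chr <- character(nrow(vars))
  for (i in seq_len(nrow(vars))) {
    if (!is.na(vars$gene_id[i])) {
      grow <- genes[genes$gene_id == vars$gene_id[i], ]
    } else if (stats::runif(1) < 0.7) {
      grow <- decoy_genes[sample.int(nrow(decoy_genes), 1), ]
      vars$gene_id[i] <- grow$gene_id
    } else {
      ch <- sample(names(chrom_lengths), 1)
      chr[i] <- ch
      pos[i] <- as.integer(floor(stats::runif(1, 1, chrom_lengths[[ch]])))
      next
    }
    chr[i] <- grow$chrom
    lo <- max(grow$start_bp - config$flank_bp, 1)
    hi <- min(grow$end_bp + config$flank_bp, chrom_lengths[[grow$chrom]])
    pos[i] <- as.integer(floor(stats::runif(1, lo, hi)))
  }
  vars[, chrom := chr][, pos_bp := pos]

  # true effect vectors
  beta <- matrix(0, nrow(vars), length(mets),
                 dimnames = list(vars$variant_id, mets))
  for (i in seq_len(nrow(vars))) {
    mech <- vars$mechanism[i]
    d <- if (mech %in% c("enzyme", "transporter")) config$d_local
         else config$d_global
    beta[i, ] <- propagate_effect(
      network, vars$gene_id[i], mech, vars$a[i], d,
      entry = if (mech == "background") vars$entry[i]
    )
  }

  # decoys: LD copies of causal sites at fixed r2 tiers, then plain nulls
  tiers <- config$ld_r2_tiers
  n_copies <- length(tiers) * nrow(vars)
  ld <- data.table::data.table(
    parent = rep(vars$variant_id, each = length(tiers)),
    r2 = rep(tiers, nrow(vars))
  )
  ld[, variant_id := paste0(parent, "_ld", rep(seq_along(tiers), nrow(vars)))]
  pidx <- match(ld$parent, vars$variant_id)
  # r2 decays with distance in real genomes: high-r2 copies sit close
  off <- as.integer(round(stats::runif(n_copies, -0.5, 0.5) * (1 - ld$r2) *
                            config$clump_window_bp))
  ld[, chrom := vars$chrom[pidx]]
  ld[, pos_bp := pmin(pmax(vars$pos_bp[pidx] + off, 1),
                      chrom_lengths[chrom])]
  n_plain <- max(config$n_decoy - n_copies, 0L)
  plain <- data.table::data.table(
    variant_id = sprintf("d%04d", seq_len(n_plain)),
    chrom = sample(names(chrom_lengths), n_plain, replace = TRUE)
  )
  plain[, pos_bp := as.integer(floor(stats::runif(.N, 1,
                                                  chrom_lengths[chrom])))]
  decoy <- data.table::rbindlist(list(
    ld[, .(variant_id, chrom, pos_bp, gene_id = NA_character_,
           mechanism = "decoy", a = 0, entry = NA_character_,
           is_causal = FALSE, ld_parent = parent, ld_r2 = r2)],
    plain[, .(variant_id, chrom, pos_bp, gene_id = NA_character_,
              mechanism = "decoy", a = 0, entry = NA_character_,
              is_causal = FALSE, ld_parent = NA_character_,
              ld_r2 = NA_real_)]
  ))
  vars[, ld_parent := NA_character_][, ld_r2 := NA_real_]
  variants <- data.table::rbindlist(list(vars, decoy), use.names = TRUE)
  variants[, cm := pos_bp * 1e-6]
  data.table::setcolorder(variants, c("variant_id", "chrom", "pos_bp", "cm"))

  # LD copies inherit an attenuated true effect (beta * r); plain decoys 0
  beta_all <- matrix(0, nrow(variants), length(mets),
                     dimnames = list(variants$variant_id, mets))
  beta_all[rownames(beta), ] <- beta
  cp <- !is.na(variants$ld_parent)
  beta_all[cp, ] <- sqrt(variants$ld_r2[cp]) *
    beta[variants$ld_parent[cp], , drop = FALSE]

  # true rg over causal (linkage-equilibrium) sites only
  bc <- beta
  ss <- colSums(bc^2)
  denom <- sqrt(outer(ss, ss))
  rg <- crossprod(bc) / denom
  rg[denom == 0] <- NA
  diag(rg)[ss > 0] <- 1
  if (anyNA(rg)) {
    met_log("simulate_architecture: some metabolites have no causal effects;",
            " their true rg is undefined")
  }
  if (is.null(labels)) labels <- between_labels(network, config$slack)
  structure(
    list(variants = variants, beta = beta_all, rg = rg, labels = labels,
         d_local = config$d_local, d_global = config$d_global,
         metabolites = mets),
    class = "met_truth"
  )
}

#' Planted between/upstream/downstream label of variants for metabolite pairs
#'
#' Expands the per-gene labels of the truth object to the causal variants.
#' Variants without an attached pathway gene are `outside` every pair.
#'
#' @param truth a `met_truth`.
#' @return data.table: `variant_id`, `met_a`, `met_b`, `label`.
#' @export
truth_variant_labels <- function(truth) {
  cv <- truth$variants[truth$variants$is_causal == TRUE, ]
  prs <- unique(truth$labels[, c("met_a", "met_b")])
  out <- data.table::CJ(variant_id = cv$variant_id, idx = seq_len(nrow(prs)))
  out[, met_a := prs$met_a[idx]][, met_b := prs$met_b[idx]][, idx := NULL]
  out[, gene_id := cv$gene_id[match(variant_id, cv$variant_id)]]
  out[, mechanism := cv$mechanism[match(variant_id, cv$variant_id)]]
  lab <- truth$labels
  out <- merge(out, lab, by = c("gene_id", "met_a", "met_b"),
               all.x = TRUE, sort = FALSE)
  out[is.na(label), label := "outside"]
  out[, .(variant_id, met_a, met_b, mechanism, label)]
}

#' Emit noisy GWAS summary statistics from a planted truth
#'
#' Standard summary-statistic sampling: `se = s0 / sqrt(n)` for every
#' variant and trait, `beta_hat = beta_true + Normal(0, se^2)`,
#' `p = 2 * pnorm(-|beta_hat| / se)`.
#'
#' @param truth a `met_truth`.
#' @param n effective GWAS sample size (> 0).
#' @param seed integer seed.
#' @param s0 per-observation noise scale (default 1).
#' @return A `sumstats` table covering every planted and decoy variant.
#' @export
emit_sumstats <- function(truth, n, seed, s0 = 1) {
  stopifnot(n > 0)
  set.seed(seed)
  v <- truth$variants
  mets <- truth$metabolites
  se <- s0 / sqrt(n)
  dt <- data.table::data.table(
    variant_id = v$variant_id, chrom = v$chrom, pos_bp = v$pos_bp, cm = v$cm,
    effect_allele = "A", other_allele = "G"
  )
  for (m in mets) {
    bh <- truth$beta[, m] + stats::rnorm(nrow(v), 0, se)
    dt[[paste0("beta_", m)]] <- bh
    dt[[paste0("se_", m)]] <- rep(se, nrow(v))
    dt[[paste0("p_", m)]] <- 2 * stats::pnorm(-abs(bh) / se)
  }
  sumstats_table(dt, mets)
}

#' LD r2 table of a planted truth, for clumping
#'
#' @param truth a `met_truth`.
#' @return data.table `variant_a`, `variant_b`, `r2` (symmetric pairs listed
#'   once; unlisted pairs have r2 = 0).
#' @export
truth_ld <- function(truth) {
  v <- truth$variants[!is.na(truth$variants$ld_parent), ]
  data.table::data.table(variant_a = v$ld_parent, variant_b = v$variant_id,
                         r2 = v$ld_r2)
}

#' Emit noisy pairwise genetic-correlation estimates
#'
#' @param truth a `met_truth`.
#' @param noise_sd estimation noise; also reported as the SE.
#' @param seed integer seed.
#' @return A `pair_cor` data.table: `met_a`, `met_b`, `rg`, `se`, plus the
#'   true value in `rg_true`. Pairs with undefined truth are flagged NA.
#' @export
emit_pair_rg <- function(truth, noise_sd, seed) {
  set.seed(seed)
  mets <- truth$metabolites
  prs <- utils::combn(sort(mets), 2)
  rg_true <- truth$rg[cbind(prs[1, ], prs[2, ])]
  out <- data.table::data.table(
    met_a = prs[1, ], met_b = prs[2, ],
    rg = rg_true + stats::rnorm(ncol(prs), 0, noise_sd),
    se = noise_sd, rg_true = rg_true
  )
  data.table::setattr(out, "class", c("pair_cor", class(out)))
  out
}

#' Tile a genome into LD blocks
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param block_size block size in bp.
#' @return data.table `chrom`, `start_bp`, `end_bp`, `block_id`; blocks tile
#'   each chromosome without overlap.
#' @export
make_blocks <- function(chrom_lengths, block_size = 2e6) {
  chrom_lengths <- unlist(chrom_lengths)
  out <- data.table::rbindlist(lapply(names(chrom_lengths), function(ch) {
    starts <- seq(1, chrom_lengths[[ch]], by = block_size)
    data.table::data.table(
      chrom = ch, start_bp = as.integer(starts),
      end_bp = as.integer(pmin(starts + block_size - 1, chrom_lengths[[ch]]))
    )
  }))
  out[, block_id := sprintf("block%04d", .I)]
  out
}

#' Emit noisy per-LD-block local heritability and covariance for a trait pair
#'
#' Per block: covariance = within-block sum of beta products of the causal
#' variants plus Normal(0, noise_sd^2) noise; local h2 likewise from squared
#' effects; reported variances equal the noise variance used.
#'
#' @param truth a `met_truth`.
#' @param blocks block table from [make_blocks()] or [read_blocks()].
#' @param pair the two metabolites (default: first two of the truth).
#' @param noise_sd estimation noise.
#' @param seed integer seed.
#' @return A `block_stats` data.table with `block_id`, interval columns,
#'   `h2_a`, `h2_b`, `cov_ab`, `var_h2_a`, `var_h2_b`, `var_cov`.
#' @export
emit_block_stats <- function(truth, blocks, pair = truth$metabolites[1:2],
                             noise_sd = 0, seed = 1L) {
  set.seed(seed)
  cv <- truth$variants[truth$variants$is_causal == TRUE, ]
  b1 <- truth$beta[cv$variant_id, pair[1]]
  b2 <- truth$beta[cv$variant_id, pair[2]]
  gr_b <- GenomicRanges::GRanges(blocks$chrom,
                                 IRanges::IRanges(blocks$start_bp,
                                                  blocks$end_bp))
  gr_v <- GenomicRanges::GRanges(cv$chrom, IRanges::IRanges(cv$pos_bp,
                                                            cv$pos_bp))
  hit <- GenomicRanges::findOverlaps(gr_v, gr_b)
  idx <- S4Vectors::subjectHits(hit)
  qry <- S4Vectors::queryHits(hit)
  agg <- function(x) {
    s <- numeric(nrow(blocks))
    t <- tapply(x[qry], idx, sum)
    s[as.integer(names(t))] <- t
    s
  }
  out <- data.table::copy(blocks)
  out[, h2_a := agg(b1^2) + stats::rnorm(.N, 0, noise_sd)]
  out[, h2_b := agg(b2^2) + stats::rnorm(.N, 0, noise_sd)]
  out[, cov_ab := agg(b1 * b2) + stats::rnorm(.N, 0, noise_sd)]
  out[, var_h2_a := noise_sd^2][, var_h2_b := noise_sd^2]
  out[, var_cov := noise_sd^2]
  data.table::setattr(out, "pair", pair)
  data.table::setattr(out, "class", c("block_stats", class(out)))
  out
}

#' Outlier filter for raw metabolite levels
#'
#' Levels are log-transformed for downstream use; exclusion is decided on the
#' raw scale. A sample is excluded for a metabolite panel if any raw level
#' exceeds the upper rule (default: median + 20 * IQR; alternative reading
#' `"20iqr"`: 20 * IQR) or falls below median / 10.
#'
#' @param raw_levels matrix or data.frame, samples x metabolites, strictly
#'   positive.
#' @param upper_rule `"median_plus_20iqr"` (default) or `"20iqr"`.
#' @return list with `levels` (log-transformed retained rows), `excluded`
#'   (logical mask per sample), `by_metabolite` (exclusion counts).
#' @export
trait_qc_filter <- function(raw_levels, upper_rule = "median_plus_20iqr") {
  x <- as.matrix(raw_levels)
  if (any(x <= 0)) stop("trait_qc_filter: non-positive levels")
  upper_rule <- match.arg(upper_rule, c("median_plus_20iqr", "20iqr"))
  bad <- matrix(FALSE, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) {
    md <- stats::median(x[, j])
    iqr <- stats::IQR(x[, j])
    hi <- if (upper_rule == "median_plus_20iqr") md + 20 * iqr else 20 * iqr
    bad[, j] <- x[, j] > hi | x[, j] < md / 10
  }
  excluded <- apply(bad, 1, any)
  list(levels = log(x[!excluded, , drop = FALSE]), excluded = excluded,
       by_metabolite = colSums(bad))
}
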