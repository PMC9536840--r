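# Shared fixtures: tiny networks, hand-built tables, and a cached default
# study so expensive generation runs once per test session.

chain_net <- function(ids = c("A", "B", "C")) {
  cfg <- met_config(topology = "chain", chain_nodes = ids)
  make_network(cfg, seed = 1)$network
}

# 5-node tree:  A - B - C,  B - D,  D - E  (enzymes named by edge)
tree5_net <- function() {
  nodes <- data.frame(id = c("A", "B", "C", "D", "E"), group = "other_aa")
  edges <- data.frame(
    substrate = c("A", "B", "B", "D"),
    product = c("B", "C", "D", "E"),
    reversible = TRUE
  )
  edges$enzymes <- lapply(seq_len(4), function(i)
    paste0("E_", edges$substrate[i], edges$product[i]))
  met_network(nodes, edges)
}

# 4-cycle A-B-C-D-A with equal arms
cycle4_net <- function() {
  nodes <- data.frame(id = c("A", "B", "C", "D"), group = "glycolysis")
  edges <- data.frame(
    substrate = c("A", "B", "C", "D"),
    product = c("B", "C", "D", "A"),
    reversible = TRUE
  )
  edges$enzymes <- lapply(1:4, function(i) paste0("E", i))
  met_network(nodes, edges)
}

# minimal sumstats over arbitrary variants/metabolites
make_ss <- function(variant_id, chrom, pos_bp, betas, ses, ps, mets) {
  dt <- data.frame(variant_id = variant_id, chrom = chrom, pos_bp = pos_bp,
                   cm = pos_bp * 1e-6, effect_allele = "A",
                   other_allele = "G")
  for (j in seq_along(mets)) {
    dt[[paste0("beta_", mets[j])]] <- betas[, j]
    dt[[paste0("se_", mets[j])]] <- ses[, j]
    dt[[paste0("p_", mets[j])]] <- ps[, j]
  }
  sumstats_table(dt, mets)
}

met_groups16 <- function(network) {
  stats::setNames(network$nodes$group, network$nodes$id)
}

# session-cached default network + labels (topology is fixed, labels are
# placement-independent)
default_network_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_network(met_config(), seed = 1)
    }
    cache
  }
})

default_labels_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- between_labels(default_network_cached()$network)
    cache
  }
})
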