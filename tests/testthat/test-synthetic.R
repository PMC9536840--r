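# Generator tests: network construction, effect propagation against a
# brute-force graph oracle, closed-form rg recovery, and the sampling models.

test_that("make_network builds the requested topologies", {
  chain <- chain_net(c("A", "B", "C"))
  expect_equal(nrow(chain$edges), 2)
  expect_equal(nrow(network_genes(chain)[gene_type == "enzyme"]), 2)

  out <- default_network_cached()
  g <- network_graph(out$network)
  expect_equal(igraph::vcount(g), 16)
  expect_equal(igraph::components(g)$no, 1)
  expect_setequal(unique(out$network$nodes$group),
                  c("glycolysis", "bcaa", "other_aa", "ketone"))
  expect_equal(sum(out$network$nodes$group == "glycolysis"), 4)
  expect_equal(sum(out$network$nodes$group == "bcaa"), 3)
  expect_equal(sum(out$network$nodes$group == "other_aa"), 6)
  expect_equal(sum(out$network$nodes$group == "ketone"), 3)
})

test_that("two seeds change gene placement but not topology or gene set", {
  a <- make_network(met_config(), seed = 2)
  b <- make_network(met_config(), seed = 3)
  expect_equal(a$network$edges, b$network$edges)
  expect_identical(sort(a$genes$gene_id[!grepl("^DECOY", a$genes$gene_id)]),
                   sort(b$genes$gene_id[!grepl("^DECOY", b$genes$gene_id)]))
  shared <- intersect(a$genes$gene_id, b$genes$gene_id)
  pa <- a$genes[match(shared, a$genes$gene_id), start_bp]
  pb <- b$genes[match(shared, b$genes$gene_id), start_bp]
  expect_gt(sum(pa != pb), length(shared) / 2)
})

test_that("unsatisfiable gene placement is a configuration error", {
  cfg <- met_config(chrom_lengths = c(chr1 = 1e6))
  expect_error(make_network(cfg, 1), "configuration error")
})

test_that("enzyme propagation splits signs across the perturbed edge", {
  net <- chain_net(c("A", "B"))
  b <- propagate_effect(net, "ENZ_A_B", "enzyme", 0.2, 0.5)
  expect_equal(unname(sign(b["A"])), -1)
  expect_equal(unname(sign(b["B"])), 1)
  expect_equal(unname(b["A"]), -unname(b["B"]))
})

test_that("regulator propagation is same-signed on every metabolite", {
  net <- tree5_net()
  net$regulators <- data.table::data.table(gene_id = "TF1", entry_node = "A",
                                           sign = 1)
  b <- propagate_effect(net, "TF1", "tf", 0.3, 0.5)
  expect_true(all(b > 0))
  expect_equal(unname(b["A"]), 0.3)
  expect_equal(unname(b["C"]), 0.3 * 0.25)  # two steps from entry
})

test_that("enzyme propagation matches a brute-force side/distance oracle", {
  net <- tree5_net()
  d <- 0.6; a <- 0.11
  # perturb mid edge B -> D: brute force by explicit component enumeration
  got <- propagate_effect(net, "E_BD", "enzyme", a, d)
  side_u <- c("A", "B", "C")         # component of substrate B
  side_v <- c("D", "E")              # component of product D
  dist_u <- c(A = 1, B = 0, C = 1)
  dist_v <- c(D = 0, E = 1)
  expected <- c(-a * d^dist_u[side_u], a * d^dist_v[side_v])[names(got)]
  expect_equal(got, expected)
})

test_that("cycle ties zero out and cycle sides follow the shorter path", {
  # even cycle: no ties; each node sides with its nearer endpoint
  net <- cycle4_net()
  b <- propagate_effect(net, "E1", "enzyme", 0.4, 0.5)  # edge A -> B
  expect_equal(unname(b["A"]), -0.4)
  expect_equal(unname(b["B"]), 0.4)
  expect_equal(unname(b["C"]), 0.4 * 0.5)   # closer to B around the cycle
  expect_equal(unname(b["D"]), -0.4 * 0.5)  # closer to A
  # odd cycle: the far node is equidistant from both endpoints -> no effect
  nodes <- data.frame(id = c("A", "B", "C"), group = "glycolysis")
  edges <- data.frame(substrate = c("A", "B", "C"),
                      product = c("B", "C", "A"), reversible = TRUE)
  edges$enzymes <- lapply(1:3, function(i) paste0("E", i))
  tri <- met_network(nodes, edges)
  b3 <- propagate_effect(tri, "E1", "enzyme", 0.4, 0.5)
  expect_equal(unname(b3["C"]), 0)
  expect_equal(unname(b3["A"]), -0.4)
  expect_equal(unname(b3["B"]), 0.4)
})

test_that("transporter propagation lowers cargo and raises downstream", {
  net <- default_network_cached()$network
  b <- propagate_effect(net, "TRANS_ALA", "transporter", 0.1, 0.5)
  expect_equal(unname(b["alanine"]), -0.1)
  expect_equal(unname(b["pyruvate"]), 0.05)
  expect_equal(unname(b["isoleucine"]), 0.1 * 0.5^3)
  expect_error(propagate_effect(net, "NOPE", "transporter", 0.1, 0.5),
               "not a registered")
  expect_error(propagate_effect(net, "NOPE", "enzyme", 0.1, 0.5),
               "not attached")
})

test_that("architecture truth rg matches the direct summation oracle", {
  out <- default_network_cached()
  truth <- simulate_architecture(out$network, out$genes, met_config(),
                                 seed = 7, labels = default_labels_cached())
  bc <- truth$beta[truth$variants$variant_id[truth$variants$is_causal], ]
  mets <- truth$metabolites
  for (pair in list(c("alanine", "isoleucine"), c("glucose", "acetone"),
                    c("valine", "histidine"))) {
    num <- sum(bc[, pair[1]] * bc[, pair[2]])
    den <- sqrt(sum(bc[, pair[1]]^2) * sum(bc[, pair[2]]^2))
    expect_equal(truth$rg[pair[1], pair[2]], num / den)
  }
  expect_true(isSymmetric(truth$rg))
  expect_equal(unname(diag(truth$rg)), rep(1, 16))
  expect_true(all(abs(truth$rg) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("background/TF-only architectures have all-positive rg; a single
           causal variant gives |rg| = 1", {
  out <- default_network_cached()
  cfg0 <- met_config(n_enzyme = 0L, n_transporter = 0L, n_tf = 30L,
                     n_background = 40L, n_decoy = 0L)
  tr <- simulate_architecture(out$network, out$genes, cfg0, seed = 3,
                              labels = default_labels_cached())
  off <- tr$rg[upper.tri(tr$rg)]
  expect_true(all(off > 0, na.rm = TRUE))

  cfg1 <- met_config(n_enzyme = 1L, n_transporter = 0L, n_tf = 0L,
                     n_background = 0L, n_decoy = 0L)
  tr1 <- simulate_architecture(out$network, out$genes, cfg1, seed = 3,
                               labels = default_labels_cached())
  off1 <- abs(tr1$rg[upper.tri(tr1$rg)])
  expect_equal(unname(off1[!is.na(off1)]),
               rep(1, sum(!is.na(off1))), tolerance = 1e-12)
})

test_that("planted sign structure: between-edge enzymes oppose, regulators
           agree", {
  out <- default_network_cached()
  labs <- default_labels_cached()
  truth <- simulate_architecture(out$network, out$genes, met_config(),
                                 seed = 11, labels = labs)
  cv <- truth$variants[truth$variants$is_causal == TRUE, ]
  vlab <- truth_variant_labels(truth)
  enz_between <- vlab[mechanism == "enzyme" & label == "between"]
  checked <- 0L
  for (i in seq_len(nrow(enz_between))) {
    row <- enz_between[i]
    gene <- cv$gene_id[cv$variant_id == row$variant_id]
    eidx <- metpleio:::enzyme_edges(out$network, gene)
    paths <- shortest_paths_between(out$network, row$met_a, row$met_b,
                                    slack = 0)
    crosses <- any(vapply(paths, function(p)
      any(eidx %in% metpleio:::.path_edge_idx(out$network, p)), logical(1)))
    if (!crosses) next  # between via a slack path only
    b1 <- truth$beta[row$variant_id, row$met_a]
    b2 <- truth$beta[row$variant_id, row$met_b]
    expect_lte(sign(b1) * sign(b2), 0)
    checked <- checked + 1L
  }
  expect_gt(checked, 10)
  tf_rows <- cv[cv$mechanism == "tf", ]
  for (i in seq_len(nrow(tf_rows))) {
    b <- truth$beta[tf_rows$variant_id[i], ]
    expect_true(all(sign(b) == sign(b[1])))
  }
})

test_that("generator output is bitwise-deterministic in config + seed", {
  cfg <- met_config(n_decoy_genes = 50L, n_decoy = 100L)
  s1 <- simulate_study(cfg, 5, labels = default_labels_cached())
  s2 <- simulate_study(cfg, 5, labels = default_labels_cached())
  expect_identical(s1$truth$beta, s2$truth$beta)
  expect_identical(as.data.frame(s1$sumstats), as.data.frame(s2$sumstats))
  expect_identical(as.data.frame(s1$block_stats),
                   as.data.frame(s2$block_stats))
  s3 <- simulate_study(cfg, 6, labels = default_labels_cached())
  expect_false(identical(as.data.frame(s1$sumstats),
                         as.data.frame(s3$sumstats)))
})

test_that("emit_sumstats sampling model: null p uniform, strong z certain", {
  out <- default_network_cached()
  cfg <- met_config(n_enzyme = 0L, n_transporter = 0L, n_tf = 1L,
                    n_background = 0L, n_decoy = 1000L)
  truth <- simulate_architecture(out$network, out$genes, cfg, seed = 2,
                                 labels = default_labels_cached())
  ss <- emit_sumstats(truth, n = 1e5, seed = 3)
  null_p <- ss$p_alanine[grepl("^d", ss$variant_id)]
  expect_gt(stats::ks.test(null_p, "punif")$p.value, 0.01)
  expect_equal(ss$se_alanine, rep(1 / sqrt(1e5), nrow(ss)))
  # beta_true = 10 se is genome-wide significant with probability ~ 1
  truth$beta[, "alanine"] <- 10 / sqrt(1e5)
  ss2 <- emit_sumstats(truth, n = 1e5, seed = 4)
  expect_gt(mean(ss2$p_alanine < 5e-8), 0.99)
})

test_that("pair rg and block stats are noiseless copies of truth at sd 0 and
           tile-additive", {
  out <- default_network_cached()
  truth <- simulate_architecture(out$network, out$genes, met_config(),
                                 seed = 9, labels = default_labels_cached())
  pr <- emit_pair_rg(truth, noise_sd = 0, seed = 1)
  expect_equal(pr$rg, pr$rg_true)
  blocks <- make_blocks(met_config()$chrom_lengths, 2e6)
  bs <- emit_block_stats(truth, blocks, pair = c("alanine", "glutamine"),
                         noise_sd = 0, seed = 1)
  cv <- truth$variants[truth$variants$is_causal == TRUE, ]
  b1 <- truth$beta[cv$variant_id, "alanine"]
  b2 <- truth$beta[cv$variant_id, "glutamine"]
  expect_equal(sum(bs$cov_ab), sum(b1 * b2), tolerance = 1e-12)
  expect_equal(sum(bs$h2_a), sum(b1^2), tolerance = 1e-12)
})

test_that("pair-rg estimates are unbiased at CLT precision", {
  out <- default_network_cached()
  truth <- simulate_architecture(out$network, out$genes, met_config(),
                                 seed = 4, labels = default_labels_cached())
  noise <- 0.05
  reps <- vapply(1:200, function(i) {
    emit_pair_rg(truth, noise, seed = i)$rg[1]
  }, numeric(1))
  expect_lt(abs(mean(reps) - emit_pair_rg(truth, 0, 1)$rg_true[1]),
            3 * noise / sqrt(200))
})

test_that("trait QC outlier rules match direct evaluation", {
  x <- matrix(rep(5, 20), ncol = 2)
  res <- trait_qc_filter(x)
  expect_false(any(res$excluded))          # IQR = 0: upper rule inert
  x[3, 1] <- 500                           # 100x the median
  res <- trait_qc_filter(x)
  expect_true(res$excluded[3])
  expect_equal(sum(res$excluded), 1)

  set.seed(8)
  y <- matrix(rlnorm(300, 0, 0.3), ncol = 3)
  y[sample(100, 5), 2] <- 80
  y[sample(100, 5), 3] <- 1e-4
  res <- trait_qc_filter(y)
  manual <- rep(FALSE, 100)
  for (j in 1:3) {
    md <- median(y[, j]); iqr <- IQR(y[, j])
    manual <- manual | y[, j] > md + 20 * iqr | y[, j] < md / 10
  }
  expect_equal(res$excluded, manual)
  expect_equal(res$levels, log(y[!manual, , drop = FALSE]))
  expect_error(trait_qc_filter(matrix(c(1, -1), 1)), "non-positive")
})
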