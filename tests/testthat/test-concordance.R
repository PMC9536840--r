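# lfsr machinery against numeric integration, pair selection and
# classification against predicate/truth-table oracles.

test_that("lfsr basics: symmetry at zero, lfsr >= lfdr, monotone in |z|", {
  set.seed(21)
  est <- c(0, rnorm(60, 0, 2))
  se <- runif(61, 0.5, 1.5)
  fit <- ash_lfsr(est, se)
  expect_gte(fit$lfsr[1], 0.5)              # zero estimate: sign undecidable
  expect_true(all(fit$lfsr >= fit$lfdr - 1e-12))
  expect_true(all(fit$lfsr >= 0 & fit$lfsr <= 1))
  # monotone non-increasing in |estimate|/se under the fitted prior
  g <- fit$g
  zs <- seq(0.2, 6, length.out = 15)
  lf <- ash_lfsr(zs, rep(1, 15), fixed_g = g)$lfsr
  expect_true(all(diff(lf) <= 1e-10))
})

test_that("posterior sign probabilities match numeric integration for a
           fixed three-component prior", {
  g <- list(pi = c(0.5, 0.3, 0.2), sigma = c(0, 1, 3))
  est <- c(-2.5, -0.4, 0.3, 1.1, 4, 10)
  se <- c(1, 0.8, 0.5, 1.2, 1, 1)
  got <- ash_lfsr(est, se, fixed_g = g)$lfsr
  for (j in seq_along(est)) {
    lik <- function(e) dnorm(est[j], e, se[j])
    comp <- vapply(1:3, function(k) {
      if (g$sigma[k] == 0) g$pi[k] * lik(0)
      else g$pi[k] * integrate(function(e) dnorm(e, 0, g$sigma[k]) * lik(e),
                               -Inf, Inf, rel.tol = 1e-10)$value
    }, numeric(1))
    negmass <- vapply(2:3, function(k) {
      g$pi[k] * integrate(function(e) dnorm(e, 0, g$sigma[k]) * lik(e),
                          -Inf, 0, rel.tol = 1e-10)$value
    }, numeric(1))
    tot <- sum(comp)
    p_le <- (comp[1] + sum(negmass)) / tot
    p_ge <- (comp[1] + (sum(comp[2:3]) - sum(negmass))) / tot
    expect_equal(got[j], min(p_le, p_ge), tolerance = 1e-7,
                 info = paste("obs", j))
  }
  # a 10-sigma observation under a dispersed prior is sign-certain
  expect_lt(got[6], 1e-4)
})

test_that("significant_pairs applies the three-part predicate", {
  mets <- c("m1", "m2", "m3")
  ss <- make_ss("v1", "chr1", 100, matrix(c(0.1, -0.1, 0.05), 1),
                matrix(0.01, 1, 3), matrix(c(1e-9, 1e-5, 2e-4), 1), mets)
  leads <- merge_leads(list("v1"), ss)
  pt <- data.table::data.table(
    met_a = c("m1", "m1", "m2"), met_b = c("m2", "m3", "m3"),
    rg = c(0.5, 0.5, 0.5), se = 0.05, lfsr = c(1e-4, 1e-4, 1e-4))
  sp <- significant_pairs(leads[1], pt)
  expect_equal(nrow(sp), 1)  # only (m1, m2): m3 fails suggestive
  expect_equal(sp$met_a, "m1")
  # lfsr filter removes the pair
  pt$lfsr <- 0.5
  expect_equal(nrow(significant_pairs(leads[1], pt)), 0)
  # random tables match the direct predicate
  set.seed(2)
  for (rep in 1:20) {
    ps <- 10^runif(3, -10, -3)
    ssr <- make_ss("v1", "chr1", 100, matrix(rnorm(3), 1),
                   matrix(0.01, 1, 3), matrix(ps, 1), mets)
    lr <- merge_leads(list("v1"), ssr, gw_p = 1)
    ptr <- data.table::copy(pt)
    ptr$lfsr <- runif(3, 0, 0.01)
    got <- significant_pairs(lr[1], ptr)
    want <- vapply(1:3, function(i) {
      pa <- ps[match(ptr$met_a[i], mets)]; pb <- ps[match(ptr$met_b[i], mets)]
      max(pa, pb) < 1e-4 && min(pa, pb) < 5e-8 && ptr$lfsr[i] < 0.005
    }, logical(1))
    expect_equal(nrow(got), sum(want))
  }
})

test_that("classification follows the full sign x rg-sign truth table", {
  mets <- c("m1", "m2")
  for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (sr in c(-1, 1)) {
    ss <- make_ss("v1", "chr1", 100, matrix(c(s1 * 0.1, s2 * 0.1), 1),
                  matrix(0.01, 1, 2), matrix(c(1e-9, 1e-6), 1), mets)
    leads <- merge_leads(list("v1"), ss)
    pt <- data.table::data.table(met_a = "m1", met_b = "m2", rg = sr * 0.6,
                                 se = 0.05, lfsr = 1e-4)
    cl <- classify_variant(leads[1], significant_pairs(leads[1], pt))
    want <- if (s1 * s2 != sr) "discordant" else "concordant"
    expect_equal(cl$class, want, info = sprintf("%d %d %d", s1, s2, sr))
  }
  # no significant pairs -> neither
  ssn <- make_ss("v1", "chr1", 100, matrix(c(0.1, 0.1), 1),
                 matrix(0.01, 1, 2), matrix(c(1e-9, 0.5), 1), mets)
  ln <- merge_leads(list("v1"), ssn)
  pt <- data.table::data.table(met_a = "m1", met_b = "m2", rg = 0.6,
                               se = 0.05, lfsr = 1e-4)
  expect_equal(classify_variant(ln[1], significant_pairs(ln[1], pt))$class,
               "neither")
  # corrupt zero signs guard
  ssz <- make_ss("v1", "chr1", 100, matrix(c(0, 0.1), 1),
                 matrix(0.01, 1, 2), matrix(c(1e-9, 1e-6), 1), mets)
  lz <- merge_leads(list("v1"), ssz)
  expect_error(classify_variant(lz[1], significant_pairs(lz[1], pt)),
               "undefined")
})

test_that("allele flips never change the variant class", {
  st <- simulate_study(met_config(n_decoy_genes = 50L, n_decoy = 100L), 3,
                       labels = default_labels_cached())
  res <- run_pipeline(st)
  leads <- res$leads
  flipped <- data.table::copy(leads)
  for (m in metabolites(st$sumstats)) {
    flipped[[paste0("beta_", m)]] <- -flipped[[paste0("beta_", m)]]
  }
  data.table::setattr(flipped, "metabolites", metabolites(leads))
  calls_f <- classify_leads(flipped, res$pair_rg, st$config)
  expect_equal(calls_f$calls$class, res$calls$calls$class)
})

test_that("disease direction consistency counts what it should", {
  eff <- data.frame(biomarker = c("ile", "gly", "ldl", "hdl"),
                    beta = c(0.1, -0.2, 0.3, 0.05),
                    p = c(1e-8, 1e-9, 1e-7, 0.2))
  risk <- c(ile = 1, gly = -1, ldl = 1, hdl = -1)
  res <- disease_direction_consistency(eff, risk)
  expect_equal(res$fraction, 1)  # hdl fails p_cut; others all consistent
  risk2 <- c(ile = -1, gly = -1, ldl = 1, hdl = -1)
  expect_equal(disease_direction_consistency(eff, risk2)$fraction, 2 / 3)
  # nothing passes the threshold: NA
  expect_true(is.na(disease_direction_consistency(
    transform(eff, p = 0.5), risk)$fraction))
  # counting oracle on random tables
  set.seed(31)
  for (rep in 1:20) {
    n <- 8
    eff <- data.frame(biomarker = paste0("b", 1:n), beta = rnorm(n),
                      p = 10^runif(n, -8, -2))
    risk <- setNames(sample(c(-1, 0, 1), n, TRUE), eff$biomarker)
    res <- disease_direction_consistency(eff, risk, p_cut = 1e-5)
    q <- eff$p < 1e-5 & risk != 0
    want <- if (!any(q)) NA_real_ else sum(sign(eff$beta[q]) == risk[q]) / sum(q)
    expect_equal(res$fraction, want)
  }
})

test_that("on near-noiseless data, between-pair enzyme variants are
           discordant and regulators never are", {
  out <- default_network_cached()
  cfg <- met_config(n_eff = 1e10, rg_noise_sd = 0.01,
                    n_decoy_genes = 50L, n_decoy = 100L)
  st <- simulate_study(cfg, 17, labels = default_labels_cached())
  res <- run_pipeline(st)
  tv <- st$truth$variants
  cls <- merge(res$calls$calls,
               tv[, list(variant_id, mechanism)], by = "variant_id")
  tf_cls <- cls$class[cls$mechanism == "tf"]
  expect_false(any(tf_cls == "discordant"))
  vlab <- truth_variant_labels(st$truth)
  pc <- res$calls$pair_calls
  if (nrow(pc)) {
    m <- merge(pc, vlab, by = c("variant_id", "met_a", "met_b"))
    enz_between <- m[m$mechanism == "enzyme" & m$label == "between", ]
    expect_gt(nrow(enz_between), 0)
    expect_true(all(enz_between$pair_class == "discordant"))
  }
})
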