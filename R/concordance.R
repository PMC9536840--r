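# Empirical-Bayes local false sign rates for pairwise genetic correlations,
# significant-pair selection, and discordant/concordant classification of
# lead variants against the sign of each pair's global genetic correlation.

#' Adaptive-shrinkage local false sign rate
#'
#' Fits a zero-centered normal-mixture prior with a point mass at zero,
#' g = pi0 * delta0 + sum_k pik * N(0, sigma_k^2), by penalized EM on the
#' marginal likelihood (default penalty weight 10 on the null component, as
#' in conventional adaptive shrinkage), then reports per observation
#' lfsr = min(P(effect <= 0 | data), P(effect >= 0 | data)), both inclusive
#' of the point mass. The sigma grid ascends in sqrt(2) multiplicative steps
#' from min(se)/10 to 2 * sqrt(max(est^2 - se^2, 0)).
#'
#' @param estimates,ses paired numeric vectors, `ses > 0`.
#' @param penalty penalty weight on the null component (default 10).
#' @param tol,maxit EM convergence tolerance on the penalized log-likelihood
#'   and iteration cap; non-convergence is an error reporting the final
#'   delta.
#' @param fixed_g optional list(pi, sigma) to skip the EM and evaluate
#'   posterior sign probabilities under a fixed prior (sigma[1] must be 0 for
#'   the point mass).
#' @return list: `lfsr`, `lfdr` (posterior null mass), `g` (fitted prior:
#'   `pi`, `sigma`), `loglik`, `niter`.
#' @export
ash_lfsr <- function(estimates, ses, penalty = 10, tol = 1e-8, maxit = 50000,
                     fixed_g = NULL) {
  stopifnot(length(estimates) == length(ses), all(ses > 0))
  n <- length(estimates)
  if (is.null(fixed_g)) {
    smin <- min(ses) / 10
    smax <- 2 * sqrt(max(c(estimates^2 - ses^2, 0)))
    if (smax <= smin) smax <- smin * 8
    K <- ceiling(2 * log2(smax / smin)) + 1
    sigma <- c(0, smin * sqrt(2)^(seq_len(K) - 1))
  } else {
    sigma <- fixed_g$sigma
    stopifnot(sigma[1] == 0)
  }
  # component marginal likelihood matrix: obs x components
  sd_jk <- sqrt(outer(ses^2, sigma^2, "+"))
  L <- stats::dnorm(estimates / sd_jk) / sd_jk
  if (is.null(fixed_g)) {
    K1 <- length(sigma)
    pi_k <- rep(1 / K1, K1)
    pen <- c(penalty - 1, rep(0, K1 - 1))
    obj_old <- -Inf
    niter <- 0L
    repeat {
      niter <- niter + 1L
      num <- sweep(L, 2, pi_k, "*")
      denom <- rowSums(num)
      W <- num / denom
      obj <- sum(log(denom)) + sum(pen * log(pi_k))
      pi_k <- (colSums(W) + pen) / (n + sum(pen))
      pi_k <- pmax(pi_k, 1e-300)
      if (abs(obj - obj_old) < tol) break
      if (niter >= maxit) {
        stop(sprintf(
          "ash_lfsr: EM did not converge after %d iterations (delta = %g)",
          maxit, obj - obj_old))
      }
      obj_old <- obj
    }
  } else {
    pi_k <- fixed_g$pi
    niter <- 0L
    obj <- sum(log(rowSums(sweep(L, 2, pi_k, "*"))))
  }
  num <- sweep(L, 2, pi_k, "*")
  W <- num / rowSums(num)
  # posterior of the effect within component k is
  # N(est * s2k/(s2k+se2), s2k*se2/(s2k+se2)); P(<=0) has closed form
  s2 <- outer(rep(1, n), sigma^2)
  se2 <- outer(ses^2, rep(1, length(sigma)))
  mu <- estimates * s2 / (s2 + se2)
  tau <- sqrt(s2 * se2 / (s2 + se2))
  Pneg <- stats::pnorm(0, mean = mu, sd = tau)
  Pneg[, 1] <- 0 # point mass handled separately
  p_le <- W[, 1] + rowSums((W * Pneg)[, -1, drop = FALSE])
  p_ge <- W[, 1] + rowSums((W * (1 - Pneg))[, -1, drop = FALSE])
  list(lfsr = pmin(p_le, p_ge), lfdr = W[, 1],
       g = list(pi = pi_k, sigma = sigma), loglik = obj, niter = niter)
}

#' Attach lfsr values to a pairwise correlation table
#'
#' Fits [ash_lfsr()] jointly over all pairs of the table.
#'
#' @param pair_table a `pair_cor` table (`met_a`, `met_b`, `rg`, `se`).
#' @param ... passed to [ash_lfsr()].
#' @return the table with an `lfsr` column added.
#' @export
pair_lfsr <- function(pair_table, ...) {
  ok <- !is.na(pair_table$rg)
  fit <- ash_lfsr(pair_table$rg[ok], pair_table$se[ok], ...)
  pair_table$lfsr <- NA_real_
  pair_table$lfsr[ok] <- fit$lfsr
  pair_table
}

#' Significant metabolite pairs of a lead variant
#'
#' A pair qualifies if the variant is suggestively associated with both
#' metabolites (max p < `suggestive_p`), genome-wide significant in at least
#' one (min p < `gw_p`), and the pair's genetic correlation passes the lfsr
#' filter (lfsr < `lfsr_cut`).
#'
#' @param lead one-row slice of a `leads` table.
#' @param pair_table `pair_cor` table with an `lfsr` column
#'   (see [pair_lfsr()]).
#' @param gw_p,suggestive_p,lfsr_cut thresholds.
#' @return data.table subset of `pair_table` rows qualifying for this lead.
#' @export
significant_pairs <- function(lead, pair_table, gw_p = 5e-8,
                              suggestive_p = 1e-4, lfsr_cut = 0.005) {
  pt <- data.table::as.data.table(pair_table)
  pa <- vapply(pt$met_a, function(m) lead[[paste0("p_", m)]][1], numeric(1))
  pb <- vapply(pt$met_b, function(m) lead[[paste0("p_", m)]][1], numeric(1))
  keep <- pmax(pa, pb) < suggestive_p & pmin(pa, pb) < gw_p &
    !is.na(pt$lfsr) & pt$lfsr < lfsr_cut
  pt[keep]
}

#' Classify a lead variant as discordant, concordant or neither
#'
#' Per significant pair, the variant is discordant when the product of its
#' effect signs on the two metabolites opposes the sign of the pair's global
#' genetic correlation (taken from the point estimate). The variant is
#' discordant if any significant pair is discordant, concordant if it has at
#' least one significant pair and none is discordant, and neither otherwise.
#'
#' @param lead one-row slice of a `leads` table.
#' @param pairs significant pairs from [significant_pairs()].
#' @return list: `variant_id`, `class`, `pairs` (data.table with per-pair
#'   `pair_class`).
#' @export
classify_variant <- function(lead, pairs) {
  if (!nrow(pairs)) {
    return(list(variant_id = lead$variant_id, class = "neither",
                pairs = data.table::data.table()))
  }
  b1 <- vapply(pairs$met_a, function(m) lead[[paste0("beta_", m)]][1],
               numeric(1))
  b2 <- vapply(pairs$met_b, function(m) lead[[paste0("beta_", m)]][1],
               numeric(1))
  if (any(b1 == 0 | b2 == 0 | pairs$rg == 0)) {
    stop("classify_variant: zero effect or zero rg in a significant pair; ",
         "signs undefined (corrupt input)")
  }
  disc <- sign(b1) * sign(b2) != sign(pairs$rg)
  pairs <- data.table::copy(data.table::as.data.table(pairs))
  pairs[, pair_class := ifelse(disc, "discordant", "concordant")]
  list(variant_id = lead$variant_id,
       class = if (any(disc)) "discordant" else "concordant",
       pairs = pairs)
}

#' Classify every lead variant of a study
#'
#' @param leads a `leads` table.
#' @param pair_table `pair_cor` table with `lfsr` (see [pair_lfsr()]).
#' @param config a [met_config()].
#' @return list with `calls` (variant_id, class, n_significant_pairs) and
#'   `pair_calls` (one row per significant (variant, pair) with
#'   `pair_class`).
#' @export
classify_leads <- function(leads, pair_table, config = met_config()) {
  calls <- vector("list", nrow(leads))
  pair_calls <- vector("list", nrow(leads))
  for (i in seq_len(nrow(leads))) {
    lead <- leads[i]
    sp <- significant_pairs(lead, pair_table, config$gw_p,
                            config$suggestive_p, config$lfsr_cut)
    cl <- classify_variant(lead, sp)
    calls[[i]] <- data.table::data.table(
      variant_id = cl$variant_id, class = cl$class,
      n_significant_pairs = nrow(sp)
    )
    if (nrow(sp)) {
      pair_calls[[i]] <- data.table::data.table(
        variant_id = cl$variant_id, cl$pairs[, .(met_a, met_b, pair_class)]
      )
    }
  }
  list(calls = data.table::rbindlist(calls),
       pair_calls = data.table::rbindlist(pair_calls))
}

#' Direction consistency of a variant's biomarker effects with disease risk
#'
#' Over biomarkers passing `p_cut` with a nonzero declared risk direction,
#' the fraction whose effect sign matches the risk direction.
#'
#' @param effects data.frame with `biomarker`, `beta`, `p`.
#' @param risk_directions named vector in \{-1, 0, 1\} per biomarker.
#' @param p_cut association threshold (default 1e-5).
#' @return list: `fraction` (NA if no biomarker qualifies), `table`.
#' @export
disease_direction_consistency <- function(effects, risk_directions,
                                          p_cut = 1e-5) {
  eff <- data.table::as.data.table(effects)
  eff[, risk := risk_directions[biomarker]]
  eff[, qualifies := p < p_cut & !is.na(risk) & risk != 0]
  eff[, consistent := qualifies & sign(beta) == risk]
  n <- sum(eff$qualifies)
  list(fraction = if (n == 0) NA_real_ else sum(eff$consistent) / n,
       table = eff[])
}
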