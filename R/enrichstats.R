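# Exact statistical kernels used by the enrichment analyses. Two-sided exact
# p-values follow the probability-mass rule (sum over outcomes no more
# probable than the observed one), matching the conventional defaults of
# standard exact-test implementations.

.enrich_result <- function(statistic, ci_low, ci_high, p, method, inputs) {
  structure(list(statistic = statistic, ci_low = ci_low, ci_high = ci_high,
                 p = p, method = method, inputs = inputs),
            class = "enrich_result")
}

#' @export
print.enrich_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$method, x$statistic, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Exact Poisson rate-ratio test
#'
#' Tests equality of two Poisson rates with exposures `L1_mb`, `L2_mb`
#' (megabases here, but any common exposure unit works). Inference is
#' conditional on the total count: under the null,
#' x1 ~ Binomial(x1 + x2, L1/(L1+L2)). The two-sided p-value is the exact
#' binomial probability-mass p; the CI inverts the Clopper-Pearson interval
#' on the binomial proportion q via RR = q/(1-q) * L2/L1.
#'
#' @param x1,x2 non-negative integer counts.
#' @param L1_mb,L2_mb positive exposures.
#' @param conf confidence level.
#' @return An `enrich_result` with the rate ratio (x1/L1)/(x2/L2).
#' @export
poisson_rate_test <- function(x1, L1_mb, x2, L2_mb, conf = 0.95) {
  stopifnot(x1 >= 0, x2 >= 0, x1 == round(x1), x2 == round(x2),
            L1_mb > 0, L2_mb > 0)
  if (x1 == 0 && x2 == 0) {
    stop("poisson_rate_test: undefined rate ratio with x1 = x2 = 0")
  }
  n <- x1 + x2
  q0 <- L1_mb / (L1_mb + L2_mb)
  d <- stats::dbinom(0:n, n, q0)
  p <- min(1, sum(d[d <= d[x1 + 1] * (1 + 1e-7)]))
  alpha <- 1 - conf
  qlo <- if (x1 == 0) 0 else stats::qbeta(alpha / 2, x1, x2 + 1)
  qhi <- if (x1 == n) 1 else stats::qbeta(1 - alpha / 2, x1 + 1, x2)
  to_rr <- function(q) q / (1 - q) * L2_mb / L1_mb
  rr <- (x1 / L1_mb) / (x2 / L2_mb)
  .enrich_result(rr, to_rr(qlo), if (qhi == 1) Inf else to_rr(qhi), p,
                 "poisson_rate",
                 list(x1 = x1, L1_mb = L1_mb, x2 = x2, L2_mb = L2_mb))
}

# log weights of Fisher's noncentral hypergeometric over the support
.fnch_logw <- function(row1, row2, col1, log_theta) {
  lo <- max(0, col1 - row2)
  hi <- min(row1, col1)
  x <- lo:hi
  lchoose(row1, x) + lchoose(row2, col1 - x) + x * log_theta
}

.fnch_mean <- function(row1, row2, col1, log_theta) {
  lw <- .fnch_logw(row1, row2, col1, log_theta)
  w <- exp(lw - max(lw))
  x <- (max(0, col1 - row2)):(min(row1, col1))
  sum(x * w) / sum(w)
}

#' Fisher's exact test with conditional-MLE odds ratio
#'
#' Two-sided p by the probability-mass rule over all tables with the observed
#' margins; the odds ratio is the conditional MLE solving E_theta[A] = a
#' under Fisher's noncentral hypergeometric distribution; the CI inverts the
#' one-sided tail probabilities at (1 - conf)/2. Degenerate margins give an
#' undefined OR with p = 1.
#'
#' @param a,b,c,d non-negative integer cells of the 2x2 table
#'   rows = (a, b) and (c, d).
#' @param conf confidence level.
#' @return An `enrich_result` with the conditional-MLE odds ratio.
#' @export
fisher_exact <- function(a, b, c, d, conf = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("fisher_exact: cells must be non-negative integers")
  }
  row1 <- a + b; row2 <- c + d; col1 <- a + c; col2 <- b + d
  inputs <- list(a = a, b = b, c = c, d = d)
  if (row1 == 0 || row2 == 0 || col1 == 0 || col2 == 0) {
    return(.enrich_result(NA_real_, NA_real_, NA_real_, 1, "fisher_exact",
                          inputs))
  }
  lo <- max(0, col1 - row2)
  hi <- min(row1, col1)
  dh <- stats::dhyper(lo:hi, col1, col2, row1)
  # dhyper parameterizes by column totals; index by a - lo
  p <- min(1, sum(dh[dh <= dh[a - lo + 1] * (1 + 1e-7)]))
  alpha <- 1 - conf
  solve_logt <- function(f, lower = -70, upper = 70) {
    stats::uniroot(f, c(lower, upper), tol = 1e-12)$root
  }
  or <- if (a == lo && a == hi) NA_real_
        else if (a == lo) 0
        else if (a == hi) Inf
        else exp(solve_logt(function(t) .fnch_mean(row1, row2, col1, t) - a))
  tail_ge <- function(t) { # P(X >= a | theta = exp(t))
    lw <- .fnch_logw(row1, row2, col1, t)
    w <- exp(lw - max(lw))
    sum(w[(lo:hi) >= a]) / sum(w)
  }
  tail_le <- function(t) {
    lw <- .fnch_logw(row1, row2, col1, t)
    w <- exp(lw - max(lw))
    sum(w[(lo:hi) <= a]) / sum(w)
  }
  ci_low <- if (a == lo) 0
            else exp(solve_logt(function(t) tail_ge(t) - alpha / 2))
  ci_high <- if (a == hi) Inf
             else exp(solve_logt(function(t) tail_le(t) - alpha / 2))
  .enrich_result(or, ci_low, ci_high, p, "fisher_exact", inputs)
}

#' Wilson score interval for a binomial proportion
#'
#' @param k successes, `n` trials, `conf` confidence level.
#' @param n number of trials.
#' @param conf confidence level.
#' @return numeric vector `c(low, high)`.
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  stopifnot(k >= 0, k <= n, n > 0)
  z <- stats::qnorm((1 + conf) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Fligner-Killeen two-group variance test
#'
#' Pools absolute deviations from each group's own median, ranks them
#' (midranks for ties), transforms ranks to normal scores
#' a_i = qnorm(1/2 + r_i / (2(N+1))), and compares group means of the scores
#' against a chi-squared reference with one degree of freedom.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @return list: `statistic`, `p`, `df`.
#' @export
fligner_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("fligner_test: each group needs at least 2 values")
  }
  dev <- c(abs(x - stats::median(x)), abs(y - stats::median(y)))
  grp <- rep(1:2, c(length(x), length(y)))
  N <- length(dev)
  r <- rank(dev)
  a <- stats::qnorm(0.5 + r / (2 * (N + 1)))
  abar <- mean(a)
  v <- stats::var(a)
  stat <- sum(tapply(a, grp, function(z) length(z) * (mean(z) - abar)^2)) / v
  list(statistic = unname(stat),
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE), df = 1)
}

#' Build the discordant/concordant enrichment tables
#'
#' Two 2x2 tables over classified (discordant or concordant) lead variants:
#' `gene_type` contrasts pathway-relevant enzyme-or-transporter annotations
#' against all other gene types; `between` restricts to enzyme-annotated
#' variants and contrasts those acting between at least one of their
#' defining metabolite pairs against the rest. Defining pairs are the
#' discordant pairs of a discordant variant and all significant pairs of a
#' concordant variant.
#'
#' @param calls output of [classify_leads()].
#' @param annotations output of [annotate_leads()].
#' @param labels gene-level labels from [between_labels()].
#' @return list of matrices `gene_type` and `between` (rows discordant,
#'   concordant).
#' @export
build_enrichment_tables <- function(calls, annotations, labels) {
  cl <- merge(calls$calls, annotations[, c("variant_id", "gene_id",
                                           "gene_type")],
              by = "variant_id", sort = FALSE)
  cl <- cl[cl$class %in% c("discordant", "concordant"), ]
  enztrans <- cl$gene_type %in% c("enzyme", "transporter")
  tab_type <- rbind(
    discordant = c(enz_or_trans = sum(cl$class == "discordant" & enztrans),
                   other = sum(cl$class == "discordant" & !enztrans)),
    concordant = c(enz_or_trans = sum(cl$class == "concordant" & enztrans),
                   other = sum(cl$class == "concordant" & !enztrans))
  )
  enz <- cl[cl$gene_type == "enzyme", ]
  pc <- calls$pair_calls
  between_any <- vapply(seq_len(nrow(enz)), function(i) {
    vp <- pc[pc$variant_id == enz$variant_id[i], ]
    if (enz$class[i] == "discordant") vp <- vp[vp$pair_class == "discordant", ]
    if (!nrow(vp)) return(FALSE)
    lab <- merge(vp, labels[labels$gene_id == enz$gene_id[i], ],
                 by = c("met_a", "met_b"))
    any(lab$label == "between")
  }, logical(1))
  tab_between <- rbind(
    discordant = c(between = sum(enz$class == "discordant" & between_any),
                   not_between = sum(enz$class == "discordant" & !between_any)),
    concordant = c(between = sum(enz$class == "concordant" & between_any),
                   not_between = sum(enz$class == "concordant" & !between_any))
  )
  list(gene_type = tab_type, between = tab_between)
}
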