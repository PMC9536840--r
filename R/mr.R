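# Pairwise Mendelian randomization between metabolites with Rucker model
# selection among IVW and MR-Egger, fixed- and random-effects.

#' Mendelian randomization for one exposure-outcome metabolite pair
#'
#' Instruments are the lead variants genome-wide significant in the exposure.
#' IVW: theta = sum(bX bY / sY^2) / sum(bX^2 / sY^2); Egger adds an
#' intercept to the weighted regression of bY on bX with weights 1/sY^2.
#' Q is the IVW heterogeneity statistic and Q' the Egger residual weighted
#' sum of squares. Selection: Q within its chi-squared 95% critical value
#' keeps fixed-effect IVW; otherwise a significant Q - Q' (chi-squared, 1 df)
#' moves to the Egger branch; within the chosen branch the standard error is
#' inflated multiplicatively by sqrt(Q/df) (Rucker random effects) when the
#' branch heterogeneity exceeds its critical value.
#'
#' @param leads a `leads` table.
#' @param exposure,outcome metabolite names.
#' @param gw_p instrument selection threshold on the exposure p-value.
#' @return An `mr_result` list: `exposure`, `outcome`, `n_instruments`,
#'   `method`, `estimate`, `se`, `p`, `intercept`, `intercept_se`, `Q`,
#'   `Q_prime`.
#' @export
mr_pair <- function(leads, exposure, outcome, gw_p = 5e-8) {
  sel <- leads[[paste0("p_", exposure)]] < gw_p
  J <- sum(sel)
  if (J < 3) {
    stop("mr_pair: insufficient instruments (", J, " < 3) for ", exposure)
  }
  bX <- leads[[paste0("beta_", exposure)]][sel]
  bY <- leads[[paste0("beta_", outcome)]][sel]
  sY <- leads[[paste0("se_", outcome)]][sel]
  if (all(bX == 0)) stop("mr_pair: degenerate weights (all exposure betas 0)")
  w <- 1 / sY^2
  theta_ivw <- sum(w * bX * bY) / sum(w * bX^2)
  se_ivw <- 1 / sqrt(sum(w * bX^2))
  Q <- sum(w * (bY - theta_ivw * bX)^2)
  # Egger: weighted least squares with intercept, classical (unscaled) SEs
  X <- cbind(1, bX)
  XtWX <- crossprod(X, w * X)
  coefs <- solve(XtWX, crossprod(X, w * bY))
  V <- solve(XtWX)
  resid <- bY - X %*% coefs
  Qp <- sum(w * resid^2)
  intercept <- coefs[1]; theta_egger <- coefs[2]
  int_se <- sqrt(V[1, 1]); se_egger <- sqrt(V[2, 2])

  crit_ivw <- stats::qchisq(0.95, J - 1)
  crit_egger <- stats::qchisq(0.95, J - 2)
  if (Q <= crit_ivw) {
    method <- "ivw_fe"; est <- theta_ivw; se <- se_ivw
  } else if (Q - Qp > stats::qchisq(0.95, 1)) {
    if (Qp <= crit_egger) {
      method <- "egger_fe"; est <- theta_egger; se <- se_egger
    } else {
      method <- "egger_re"; est <- theta_egger
      se <- se_egger * sqrt(max(Qp / (J - 2), 1))
    }
  } else {
    method <- "ivw_re"; est <- theta_ivw
    se <- se_ivw * sqrt(max(Q / (J - 1), 1))
  }
  structure(
    list(exposure = exposure, outcome = outcome, n_instruments = J,
         method = method, estimate = est, se = se,
         p = 2 * stats::pnorm(-abs(est) / se), intercept = intercept,
         intercept_se = int_se, Q = Q, Q_prime = Qp),
    class = "mr_result"
  )
}

#' All-pairs Mendelian randomization matrix
#'
#' @param leads a `leads` table.
#' @param gw_p instrument threshold.
#' @return data.table with one row per ordered pair having >= 3 instruments.
#' @export
mr_all_pairs <- function(leads, gw_p = 5e-8) {
  mets <- metabolites(leads)
  out <- list()
  for (ex in mets) {
    for (oc in setdiff(mets, ex)) {
      res <- tryCatch(mr_pair(leads, ex, oc, gw_p), error = function(e) NULL)
      if (is.null(res)) next
      out[[paste(ex, oc)]] <- data.table::as.data.table(
        res[c("exposure", "outcome", "n_instruments", "method", "estimate",
              "se", "p", "intercept", "Q", "Q_prime")])
    }
  }
  data.table::rbindlist(out)
}
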