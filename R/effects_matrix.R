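# Normalization of the lead-variant x metabolite effect matrix for structure
# visualization and export: per column, effect sizes are divided by their
# standard error, rank-based inverse-normal transformed and standardized;
# each row is then sign-aligned to a non-negative median across metabolites.

#' Normalize the lead-variant effect matrix
#'
#' @param leads a `leads` table.
#' @param offset rank offset convention: `"half"` uses (r - 0.5)/n (default),
#'   `"blom"` uses (r - 3/8)/(n + 1/4). Midranks are used for ties.
#' @return list of class `effect_matrix`: `scores` (variants x metabolites),
#'   `flipped` (logical per row).
#' @export
normalize_effects <- function(leads, offset = c("half", "blom")) {
  offset <- match.arg(offset)
  mets <- metabolites(leads)
  z <- sapply(mets, function(m) {
    leads[[paste0("beta_", m)]] / leads[[paste0("se_", m)]]
  })
  z <- matrix(z, nrow = nrow(leads),
              dimnames = list(leads$variant_id, mets))
  n <- nrow(z)
  q <- apply(z, 2, function(col) {
    r <- rank(col, ties.method = "average")
    u <- if (offset == "half") (r - 0.5) / n else (r - 3 / 8) / (n + 1 / 4)
    stats::qnorm(u)
  })
  q <- matrix(q, nrow = n, dimnames = dimnames(z))
  q <- scale(q)
  flipped <- apply(q, 1, stats::median) < 0
  q[flipped, ] <- -q[flipped, , drop = FALSE]
  structure(list(scores = q, flipped = flipped), class = "effect_matrix")
}
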