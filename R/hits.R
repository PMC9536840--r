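# Per-trait greedy LD clumping and cross-metabolite merging of GWAS hits
# into lead variants. Both stages use the same deterministic tie-break:
# ascending p, then (chrom, pos).

#' Greedy LD clumping of one trait's associations
#'
#' Repeatedly takes the unassigned variant with the smallest p < `clump_p`
#' as an index and assigns to it all unassigned variants with p < `clump_p`
#' within `clump_window_bp` and with r2 > `clump_r2`. Ties in p are broken
#' by ascending (chrom, pos_bp). The same p threshold applies to index and
#' assigned variants.
#'
#' @param sumstats a `sumstats` table.
#' @param ld LD information: data.frame with columns `variant_a`,
#'   `variant_b`, `r2` (unordered pairs listed once; missing pairs are
#'   r2 = 0). Required - there is no distance-only fallback.
#' @param trait metabolite name.
#' @param clump_p,clump_r2,clump_window_bp clumping parameters.
#' @return Character vector of index variant ids in discovery order.
#' @export
clump <- function(sumstats, ld, trait, clump_p = 1e-4, clump_r2 = 0.01,
                  clump_window_bp = 1e6) {
  if (missing(ld) || is.null(ld)) {
    stop("clump: no LD information supplied (r2 pair table required)")
  }
  ld <- data.table::as.data.table(ld)
  p <- sumstats[[paste0("p_", trait)]]
  if (is.null(p)) stop("clump: no p-value column for trait ", trait)
  cand <- data.table::data.table(
    variant_id = sumstats$variant_id, chrom = sumstats$chrom,
    pos_bp = sumstats$pos_bp, p = p
  )[p < clump_p]
  if (!nrow(cand)) return(character())
  data.table::setorder(cand, p, chrom, pos_bp)
  # symmetric r2 lookup
  pairs <- data.table::rbindlist(list(
    ld[, .(a = variant_a, b = variant_b, r2)],
    ld[, .(a = variant_b, b = variant_a, r2)]
  ))
  assigned <- logical(nrow(cand))
  idx <- character()
  for (i in seq_len(nrow(cand))) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    idx <- c(idx, cand$variant_id[i])
    near <- which(!assigned & cand$chrom == cand$chrom[i] &
                    abs(cand$pos_bp - cand$pos_bp[i]) <= clump_window_bp)
    if (!length(near)) next
    linked <- pairs[a == cand$variant_id[i] & b %in% cand$variant_id[near] &
                      r2 > clump_r2]
    if (nrow(linked)) {
      assigned[match(linked$b, cand$variant_id)] <- TRUE
    }
  }
  idx
}

#' Merge per-trait clump indices into cross-metabolite lead variants
#'
#' Pools indices over traits, sorts by minimum p across metabolites (ties by
#' chrom, pos), and greedily keeps each variant unless it lies within
#' `merge_cm` of an already-kept lead on the same chromosome. Only leads with
#' a genome-wide significant association in at least one metabolite are
#' retained.
#'
#' @param index_lists list (one element per trait) of index variant ids from
#'   [clump()].
#' @param sumstats the `sumstats` table the indices refer to.
#' @param merge_cm merge radius in centimorgans.
#' @param gw_p genome-wide significance threshold.
#' @param suggestive_p suggestive threshold for the per-lead metabolite sets.
#' @return A `leads` data.table: `variant_id`, `chrom`, `pos_bp`, `cm`,
#'   `min_p`, list columns `gw_metabolites` and `suggestive_metabolites`, and
#'   the per-metabolite beta/se/p triplets.
#' @export
merge_leads <- function(index_lists, sumstats, merge_cm = 0.1, gw_p = 5e-8,
                        suggestive_p = 1e-4) {
  mets <- metabolites(sumstats)
  pool <- unique(unlist(index_lists))
  dt <- data.table::as.data.table(sumstats)[variant_id %in% pool]
  if (!nrow(dt)) {
    out <- dt
  } else {
    pcols <- paste0("p_", mets)
    dt[, min_p := do.call(pmin, .SD), .SDcols = pcols]
    data.table::setorder(dt, min_p, chrom, pos_bp)
    keep <- logical(nrow(dt))
    for (i in seq_len(nrow(dt))) {
      kept <- which(keep)
      if (length(kept)) {
        same <- dt$chrom[kept] == dt$chrom[i]
        if (any(same & abs(dt$cm[kept] - dt$cm[i]) < merge_cm)) next
      }
      keep[i] <- TRUE
    }
    out <- dt[keep]
  }
  pm <- as.matrix(out[, paste0("p_", mets), with = FALSE])
  gw <- lapply(seq_len(nrow(out)), function(i) mets[pm[i, ] < gw_p])
  sug <- lapply(seq_len(nrow(out)), function(i) mets[pm[i, ] < suggestive_p])
  out[, gw_metabolites := gw]
  out[, suggestive_metabolites := sug]
  out <- out[lengths(gw_metabolites) > 0]
  data.table::setattr(out, "metabolites", mets)
  data.table::setattr(out, "class", c("leads", class(out)))
  out
}
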