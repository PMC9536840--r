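# Deterministic single-gene assignment per lead variant. The rule emulates
# manual curation with a fixed priority over gene types and a biological
# relevance check for distal enzymes; the decisive downstream quantity is the
# assigned gene *type*, which is robust to near-ties among same-type genes.

.type_priority <- c(enzyme = 1, transporter = 2, tf = 3, general = 4)

#' Distance from a variant position to a gene
#'
#' 0 if the position falls within the gene boundaries, otherwise the distance
#' to the closer of start and end; infinite across chromosomes.
#'
#' @param pos_bp,chrom variant position.
#' @param gene one-row slice of a `gene_table` (or a list with `chrom`,
#'   `start_bp`, `end_bp`).
#' @return distance in bp (0, positive integer, or `Inf`).
#' @export
variant_gene_distance <- function(pos_bp, chrom, gene) {
  if (chrom != gene$chrom) return(Inf)
  if (pos_bp >= gene$start_bp && pos_bp <= gene$end_bp) return(0)
  min(abs(pos_bp - gene$start_bp), abs(pos_bp - gene$end_bp))
}

#' Assign a single gene and gene type to a lead variant
#'
#' Candidates are all known-function genes within `flank_bp`, plus enzyme
#' genes within `enzyme_flank_bp` whose relevant metabolites intersect the
#' variant's suggestive metabolite set (the operationalization of
#' "biologically relevant"). Among candidates the gene type has priority
#' enzyme > transporter > tf > general; within a tier the gene with the
#' largest overlap between its relevant metabolites and the variant's
#' suggestive set wins, ties broken by smaller distance, then gene id. When
#' no candidate exists, known-function genes are retried within
#' `fallback_flank_bp`; failing that the variant is annotated `unknown`.
#'
#' @param variant list/row with `variant_id`, `chrom`, `pos_bp`.
#' @param genes a `gene_table`.
#' @param suggestive_mets metabolites the variant is suggestively associated
#'   with (p < suggestive threshold).
#' @param config a [met_config()] supplying the three windows.
#' @return list: `variant_id`, `gene_id`, `gene_type`, `distance_bp`,
#'   `window_used_bp`, `is_closest_gene`, `n_relevant`.
#' @export
assign_gene <- function(variant, genes, suggestive_mets,
                        config = met_config()) {
  same <- genes[genes$chrom == variant$chrom, ]
  if (!nrow(same)) {
    return(list(variant_id = variant$variant_id, gene_id = NA_character_,
                gene_type = "unknown", distance_bp = NA_real_,
                window_used_bp = config$fallback_flank_bp,
                is_closest_gene = NA, n_relevant = 0L))
  }
  d <- abs(pmin(pmax(variant$pos_bp, same$start_bp), same$end_bp) -
             variant$pos_bp)
  overlap <- vapply(same$relevant_metabolites,
                    function(r) length(intersect(r, suggestive_mets)),
                    integer(1))
  known <- same$gene_type != "unknown"
  closest_gene <- same$gene_id[which.min(d)]

  pick <- function(sel, window) {
    if (!any(sel)) return(NULL)
    cand <- data.table::data.table(
      gene_id = same$gene_id[sel], gene_type = same$gene_type[sel],
      d = d[sel], overlap = overlap[sel],
      prio = .type_priority[same$gene_type[sel]]
    )
    data.table::setorder(cand, prio, -overlap, d, gene_id)
    got <- cand[1]
    list(variant_id = variant$variant_id, gene_id = got$gene_id,
         gene_type = got$gene_type, distance_bp = got$d,
         window_used_bp = if (got$d > config$flank_bp &&
                              got$gene_type == "enzyme")
           config$enzyme_flank_bp else window,
         is_closest_gene = got$gene_id == closest_gene,
         n_relevant = got$overlap)
  }

  primary <- (known & d <= config$flank_bp) |
    (same$gene_type == "enzyme" & d <= config$enzyme_flank_bp & overlap > 0)
  res <- pick(primary, config$flank_bp)
  if (!is.null(res)) return(res)
  res <- pick(known & d <= config$fallback_flank_bp, config$fallback_flank_bp)
  if (!is.null(res)) return(res)
  list(variant_id = variant$variant_id, gene_id = NA_character_,
       gene_type = "unknown", distance_bp = NA_real_,
       window_used_bp = config$fallback_flank_bp, is_closest_gene = NA,
       n_relevant = 0L)
}

#' Annotate every lead variant with a gene and gene type
#'
#' @param leads a `leads` table from [merge_leads()].
#' @param genes a `gene_table`.
#' @param config a [met_config()].
#' @return data.table of [assign_gene()] results, one row per lead.
#' @export
annotate_leads <- function(leads, genes, config = met_config()) {
  rows <- lapply(seq_len(nrow(leads)), function(i) {
    ann <- assign_gene(
      list(variant_id = leads$variant_id[i], chrom = leads$chrom[i],
           pos_bp = leads$pos_bp[i]),
      genes, leads$suggestive_metabolites[[i]], config
    )
    data.table::as.data.table(ann)
  })
  data.table::rbindlist(rows)
}

#' Assign genes to biochemical groups by their associated metabolites
#'
#' For each annotated gene, (variant, metabolite) associations at
#' p < `suggestive_p` over that gene's variants are counted per biochemical
#' group; the gene is assigned to the argmax group, with all tied groups
#' retained.
#'
#' @param annotations output of [annotate_leads()].
#' @param leads the matching `leads` table.
#' @param met_groups named character vector mapping metabolite id -> group.
#' @param suggestive_p association threshold.
#' @return data.table `gene_id`, `groups` (list column of tied top groups).
#' @export
assign_gene_groups <- function(annotations, leads, met_groups,
                               suggestive_p = 1e-4) {
  ann <- annotations[!is.na(annotations$gene_id), ]
  mets <- metabolites(leads)
  out <- lapply(unique(ann$gene_id), function(g) {
    vids <- ann$variant_id[ann$gene_id == g]
    counts <- stats::setNames(numeric(0), character(0))
    for (vid in vids) {
      i <- match(vid, leads$variant_id)
      pv <- unlist(leads[i, paste0("p_", mets), with = FALSE])
      hit_groups <- met_groups[mets[pv < suggestive_p]]
      for (gr in hit_groups) {
        counts[gr] <- if (is.na(counts[gr])) 1 else counts[gr] + 1
      }
    }
    groups <- if (length(counts)) names(counts)[counts == max(counts)]
              else character()
    data.table::data.table(gene_id = g, groups = list(sort(groups)))
  })
  data.table::rbindlist(out)
}
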