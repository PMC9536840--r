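# Graph logic for metabolite pairs: admissible near-shortest biochemical
# paths, "between" membership of genes, upstream/downstream attribution, and
# genomic region construction for gene sets.

#' Admissible near-shortest paths between two metabolites
#'
#' All simple paths of length at most L* + `slack`, where L* is the shortest
#' path length. Edges are traversable in both directions: even one-way
#' reactions couple their reactant and product levels bidirectionally
#' (Le Chatelier reasoning), so no directionality filter is applied and
#' collider-containing routes are admissible.
#'
#' @param network a `met_network`.
#' @param m1,m2 distinct metabolite ids.
#' @param slack admissible extra length over the shortest path (default 1).
#' @return List of paths (character vectors of node ids, endpoints included).
#'   Empty list, with a warning, for a disconnected pair.
#' @export
shortest_paths_between <- function(network, m1, m2, slack = 1) {
  stopifnot(m1 != m2)
  g <- network_graph(network)
  stopifnot(m1 %in% igraph::V(g)$name, m2 %in% igraph::V(g)$name)
  lstar <- igraph::distances(g, v = m1, to = m2)[1, 1]
  if (!is.finite(lstar)) {
    warning("shortest_paths_between: ", m1, " and ", m2, " are disconnected")
    return(list())
  }
  paths <- igraph::all_simple_paths(g, from = m1, to = m2,
                                    cutoff = lstar + slack)
  paths <- Filter(function(p) length(p) - 1 <= lstar + slack, paths)
  lapply(paths, function(p) igraph::V(g)$name[p])
}

.path_edge_idx <- function(network, path) {
  # indices into network$edges crossed by a node path, either orientation
  if (length(path) < 2) return(integer())
  key <- paste(pmin(network$edges$substrate, network$edges$product),
               pmax(network$edges$substrate, network$edges$product))
  steps <- paste(pmin(path[-length(path)], path[-1]),
                 pmax(path[-length(path)], path[-1]))
  which(key %in% steps)
}

#' Classify a gene as between / upstream / downstream / outside a pair
#'
#' A gene acts *between* a metabolite pair if it encodes an enzyme catalyzing
#' a reaction on any admissible near-shortest path connecting them, or a
#' transporter whose cargo includes any node of such a path (endpoints
#' included). Otherwise the gene is placed by directed reachability on the
#' canonical substrate-to-product orientation: genes attaching to ancestors
#' of the path region are `upstream` (regulators at entry nodes fall here),
#' genes attaching to strict descendants are `downstream`, and unattached or
#' unreachable genes are `outside`. The label is symmetric in (m1, m2).
#'
#' @param network a `met_network`.
#' @param gene gene id (pathway gene or not).
#' @param pair character vector of two metabolite ids.
#' @param slack see [shortest_paths_between()].
#' @return list with fields `gene_id`, `pair`, `label`, `path_length`.
#' @export
between_membership <- function(network, gene, pair, slack = 1) {
  m1 <- pair[1]; m2 <- pair[2]
  paths <- shortest_paths_between(network, m1, m2, slack)
  region <- unique(unlist(paths))
  plen <- if (length(paths)) min(lengths(paths)) - 1 else NA_integer_
  res <- function(label) list(gene_id = gene, pair = c(m1, m2),
                              label = label, path_length = plen)
  ng <- network_genes(network)
  row <- ng[ng$gene_id == gene, ]
  if (!nrow(row)) return(res("outside"))
  type <- row$gene_type[1]
  attach <- unlist(row$attach)

  if (type == "enzyme" && length(region)) {
    eidx <- enzyme_edges(network, gene)
    on_path <- any(vapply(paths, function(p)
      any(eidx %in% .path_edge_idx(network, p)), logical(1)))
    if (on_path) return(res("between"))
  }
  if (type == "transporter" && length(region)) {
    if (any(attach %in% region)) return(res("between"))
  }
  if (!length(region)) return(res("outside"))

  dg <- network_graph(network, directed = TRUE)
  anc <- unique(unlist(lapply(region, function(v)
    igraph::V(dg)$name[igraph::subcomponent(dg, v, mode = "in")])))
  dec <- unique(unlist(lapply(region, function(v)
    igraph::V(dg)$name[igraph::subcomponent(dg, v, mode = "out")])))
  up <- setdiff(anc, region)
  down <- setdiff(dec, region)
  if (any(attach %in% up)) return(res("upstream"))
  if (any(attach %in% down)) return(res("downstream"))
  if (any(attach %in% region)) {
    # attached inside the region without qualifying biochemistry (e.g. a
    # regulator whose entry node lies on the path): treat as upstream, since
    # it modulates flux into the region
    return(res("upstream"))
  }
  res("outside")
}

#' Between/upstream/downstream labels for all pathway genes and all pairs
#'
#' Convenience table used by the synthetic-truth generator and the
#' enrichment tables; one row per (gene, unordered metabolite pair).
#'
#' @param network a `met_network`.
#' @param slack see [shortest_paths_between()].
#' @return data.table with `gene_id`, `met_a`, `met_b`, `label`.
#' @export
between_labels <- function(network, slack = 1) {
  ids <- network$nodes$id
  prs <- utils::combn(sort(ids), 2)
  ng <- network_genes(network)
  dg <- network_graph(network, directed = TRUE)
  gene_eidx <- lapply(ng$gene_id, function(g) enzyme_edges(network, g))
  out <- vector("list", ncol(prs))
  for (j in seq_len(ncol(prs))) {
    paths <- suppressWarnings(
      shortest_paths_between(network, prs[1, j], prs[2, j], slack))
    region <- unique(unlist(paths))
    path_eidx <- unique(unlist(lapply(paths, .path_edge_idx,
                                      network = network)))
    anc <- unique(unlist(lapply(region, function(v)
      igraph::V(dg)$name[igraph::subcomponent(dg, v, mode = "in")])))
    dec <- unique(unlist(lapply(region, function(v)
      igraph::V(dg)$name[igraph::subcomponent(dg, v, mode = "out")])))
    up <- setdiff(anc, region)
    down <- setdiff(dec, region)
    labs <- vapply(seq_len(nrow(ng)), function(i) {
      type <- ng$gene_type[i]
      attach <- unlist(ng$attach[[i]])
      if (length(region)) {
        if (type == "enzyme" && any(gene_eidx[[i]] %in% path_eidx)) {
          return("between")
        }
        if (type == "transporter" && any(attach %in% region)) {
          return("between")
        }
      } else {
        return("outside")
      }
      if (any(attach %in% up)) return("upstream")
      if (any(attach %in% down)) return("downstream")
      if (any(attach %in% region)) return("upstream")
      "outside"
    }, character(1))
    out[[j]] <- data.table::data.table(gene_id = ng$gene_id,
                                       met_a = prs[1, j], met_b = prs[2, j],
                                       label = labs)
  }
  data.table::rbindlist(out)
}

#' Union of flanked gene regions
#'
#' Each gene is extended by `flank_bp` on both sides, truncated at the
#' chromosome ends, and the extended intervals are union-merged.
#'
#' @param gene_ids genes to include.
#' @param genes a `gene_table`.
#' @param flank_bp flank in bp.
#' @param chrom_lengths named vector of chromosome lengths.
#' @return list with `intervals` (data.table chrom/start_bp/end_bp, disjoint
#'   and sorted) and `total_mb` (total length in megabases).
#' @export
region_union <- function(gene_ids, genes, flank_bp, chrom_lengths) {
  sel <- genes[genes$gene_id %in% gene_ids, ]
  stopifnot(nrow(sel) == length(unique(gene_ids)))
  chrom_lengths <- unlist(chrom_lengths)
  start <- pmax(sel$start_bp - flank_bp, 1)
  end <- pmin(sel$end_bp + flank_bp, chrom_lengths[sel$chrom])
  gr <- GenomicRanges::GRanges(sel$chrom, IRanges::IRanges(start, end))
  red <- GenomicRanges::reduce(gr)
  out <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start_bp = GenomicRanges::start(red),
    end_bp = GenomicRanges::end(red)
  )
  data.table::setorder(out, chrom, start_bp)
  list(intervals = out, total_mb = sum(out$end_bp - out$start_bp + 1) / 1e6)
}
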