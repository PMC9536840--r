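# Metabolic reaction network: metabolite nodes grouped by biochemistry, with
# enzyme genes on reaction edges, transporter genes attached to their cargo
# metabolites, and regulator (TF) genes attached to entry nodes.

#' Construct a metabolite reaction network
#'
#' @param nodes data.frame with columns `id` and `group`
#'   (one of `glycolysis`, `bcaa`, `other_aa`, `ketone`).
#' @param edges data.frame with columns `substrate`, `product`, `enzymes`
#'   (list column of gene ids) and `reversible` (logical). Substrate/product
#'   orientation records the canonical reaction direction; all traversal for
#'   path logic is bidirectional.
#' @param transporters named list: gene id -> character vector of cargo
#'   metabolite ids.
#' @param regulators data.frame with columns `gene_id`, `entry_node`, `sign`.
#' @return A `met_network` list.
#' @export
met_network <- function(nodes, edges,
                        transporters = list(),
                        regulators = data.frame(gene_id = character(),
                                                entry_node = character(),
                                                sign = numeric())) {
  nodes <- data.table::as.data.table(nodes)
  edges <- data.table::as.data.table(edges)
  regulators <- data.table::as.data.table(regulators)
  if (any(edges$substrate == edges$product)) {
    stop("met_network: self-loop edges are not allowed")
  }
  stopifnot(all(c(edges$substrate, edges$product) %in% nodes$id))
  net <- structure(
    list(nodes = nodes, edges = edges, transporters = transporters,
         regulators = regulators),
    class = "met_network"
  )
  g <- network_graph(net)
  if (igraph::components(g)$no != 1) {
    stop("met_network: reaction graph must be connected")
  }
  net
}

#' Undirected/directed igraph views of a network
#' @param network a `met_network`.
#' @param directed orient edges substrate -> product.
#' @return an igraph graph whose edges carry an `eidx` attribute indexing
#'   `network$edges`.
#' @export
network_graph <- function(network, directed = FALSE) {
  el <- as.matrix(network$edges[, c("substrate", "product")])
  g <- igraph::graph_from_edgelist(el, directed = directed)
  g <- igraph::set_edge_attr(g, "eidx", value = seq_len(nrow(el)))
  missing_nodes <- setdiff(network$nodes$id, igraph::V(g)$name)
  if (length(missing_nodes)) g <- igraph::add_vertices(g, length(missing_nodes),
                                                       name = missing_nodes)
  g
}

#' All pathway genes of a network with their attachment and type
#' @param network a `met_network`.
#' @return data.table: `gene_id`, `gene_type`, `attach` (list of node ids),
#'   `edge_idx` (enzyme edge indices, NA otherwise).
#' @export
network_genes <- function(network) {
  enz <- data.table::rbindlist(lapply(seq_len(nrow(network$edges)), function(i) {
    data.table::data.table(
      gene_id = unlist(network$edges$enzymes[[i]]),
      gene_type = "enzyme",
      attach = list(c(network$edges$substrate[i], network$edges$product[i])),
      edge_idx = i
    )
  }))
  # enzymes shared by several edges collapse to one row with all attachments
  if (nrow(enz) && anyDuplicated(enz$gene_id)) {
    enz <- enz[, .(gene_type = "enzyme",
                   attach = list(unique(unlist(attach))),
                   edge_idx = edge_idx[1]), by = gene_id]
  }
  trn <- if (length(network$transporters)) data.table::data.table(
    gene_id = names(network$transporters), gene_type = "transporter",
    attach = unname(lapply(network$transporters, identity)),
    edge_idx = NA_integer_
  ) else NULL
  reg <- if (nrow(network$regulators)) data.table::data.table(
    gene_id = network$regulators$gene_id, gene_type = "tf",
    attach = as.list(network$regulators$entry_node),
    edge_idx = NA_integer_
  ) else NULL
  data.table::rbindlist(list(enz, trn, reg), use.names = TRUE)
}

#' Edge indices a gene catalyzes
#' @keywords internal
enzyme_edges <- function(network, gene_id) {
  which(vapply(network$edges$enzymes,
               function(e) gene_id %in% unlist(e), logical(1)))
}

# The curated 16-metabolite topology: glycolysis/TCA entry points, alanine and
# glycine feeding pyruvate, glutaminolysis into citrate, aromatic amino acid
# degradation into acetoacetate, BCAA catabolism into the TCA cycle, ketone
# body interconversion, and a gluconeogenic lactate->glucose edge closing the
# Cori cycle. Every solid edge may summarize several reaction steps.
.metabolism16 <- function() {
  nodes <- data.table::data.table(
    id = c("glucose", "pyruvate", "lactate", "citrate",
           "isoleucine", "leucine", "valine",
           "alanine", "phenylalanine", "tyrosine", "glutamine", "histidine",
           "glycine", "acetoacetate", "acetone", "hydroxybutyrate"),
    group = c(rep("glycolysis", 4), rep("bcaa", 3), rep("other_aa", 6),
              rep("ketone", 3))
  )
  e <- function(s, p, g, rev = FALSE) {
    data.table::data.table(substrate = s, product = p, enzymes = list(list(g)),
                           reversible = rev)
  }
  edges <- data.table::rbindlist(list(
    e("glucose", "pyruvate", "ENZ_GLC_PYR", TRUE),
    e("pyruvate", "lactate", "ENZ_PYR_LAC", TRUE),
    e("lactate", "glucose", "ENZ_LAC_GLC"),
    e("pyruvate", "citrate", "ENZ_PYR_CIT"),
    e("alanine", "pyruvate", "ENZ_ALA_PYR", TRUE),
    e("glycine", "pyruvate", "ENZ_GLY_PYR", TRUE),
    e("glutamine", "citrate", "ENZ_GLN_CIT"),
    e("histidine", "glutamine", "ENZ_HIS_GLN"),
    e("phenylalanine", "tyrosine", "ENZ_PHE_TYR"),
    e("tyrosine", "acetoacetate", "ENZ_TYR_ACA"),
    e("pyruvate", "acetoacetate", "ENZ_PYR_ACA"),
    e("isoleucine", "citrate", "ENZ_ILE_CIT"),
    e("valine", "citrate", "ENZ_VAL_CIT"),
    e("leucine", "acetoacetate", "ENZ_LEU_ACA"),
    e("acetoacetate", "acetone", "ENZ_ACA_ACE"),
    e("acetoacetate", "hydroxybutyrate", "ENZ_ACA_BHB", TRUE)
  ))
  transporters <- list(
    TRANS_ALA = "alanine",
    TRANS_BCAA = c("isoleucine", "leucine", "valine"),
    TRANS_GLN = "glutamine",
    TRANS_GLC = "glucose",
    TRANS_KET = c("acetoacetate", "hydroxybutyrate")
  )
  regulators <- data.table::data.table(
    gene_id = c("TF_LIPO", "TF_AMINO", "TF_KETO", "TF_CATAB", "TF_BCAA",
                "TF_GLY"),
    entry_node = c("glucose", "phenylalanine", "leucine", "histidine",
                   "valine", "glycine"),
    sign = rep(1, 6)
  )
  met_network(nodes, edges, transporters, regulators)
}

.chain_network <- function(node_ids, groups = NULL) {
  n <- length(node_ids)
  if (is.null(groups)) groups <- rep("other_aa", n)
  nodes <- data.table::data.table(id = node_ids, group = groups)
  edges <- data.table::data.table(
    substrate = node_ids[-n], product = node_ids[-1],
    enzymes = lapply(seq_len(n - 1),
                     function(i) paste0("ENZ_", node_ids[i], "_",
                                        node_ids[i + 1])),
    reversible = TRUE
  )
  met_network(nodes, edges)
}

#' Generate a metabolic network and place its genes on a synthetic genome
#'
#' The reaction topology is deterministic for a given configuration (the
#' curated 16-metabolite graph by default, or an explicit chain); the seed
#' controls only genomic placement of pathway and decoy genes. Pathway genes
#' are placed non-overlapping with a minimum spacing so distinct pathway gene
#' sets occupy distinct LD blocks, as for real metabolic genes; decoy genes
#' (general cell function or unknown) are interspersed uniformly.
#'
#' @param config a [met_config()]; fields used: `topology`, `chrom_lengths`,
#'   `n_decoy_genes`, `gene_length`, `min_pathway_gene_spacing`.
#' @param seed integer seed.
#' @return list with elements `network` (a `met_network`) and `genes`
#'   (a `gene_table` holding pathway plus decoy genes).
#' @export
make_network <- function(config = met_config(), seed = config$seed) {
  set.seed(seed)
  network <- switch(
    config$topology,
    metabolism16 = .metabolism16(),
    chain = .chain_network(config$chain_nodes),
    stop("make_network: unknown topology ", config$topology)
  )
  pg <- network_genes(network)
  chrom_lengths <- unlist(config$chrom_lengths)
  glen <- config$gene_length
  spacing <- config$min_pathway_gene_spacing
  n_path <- nrow(pg)
  n_decoy <- config$n_decoy_genes
  capacity <- sum(pmax(floor(chrom_lengths / spacing) - 1, 0))
  if (n_path > capacity) {
    stop("make_network: configuration error - cannot place ", n_path,
         " pathway genes with ", spacing, " bp spacing on a ",
         sum(chrom_lengths), " bp genome")
  }
  if ((n_path + n_decoy) * glen * 2 > sum(chrom_lengths)) {
    stop("make_network: configuration error - too many genes for genome length")
  }
  # spaced placement for pathway genes: deal out slots, jitter within slot
  slots <- data.table::rbindlist(lapply(names(chrom_lengths), function(ch) {
    k <- max(floor(chrom_lengths[[ch]] / spacing) - 1, 0)
    if (k == 0) return(NULL)
    data.table::data.table(chrom = ch, slot_start = spacing * seq_len(k))
  }))
  pick <- slots[sample.int(nrow(slots), n_path)]
  jitter <- floor(stats::runif(n_path, 0, spacing - glen - 1))
  path_genes <- data.table::data.table(
    gene_id = pg$gene_id, chrom = pick$chrom,
    start_bp = as.integer(pick$slot_start + jitter),
    gene_type = pg$gene_type
  )
  path_genes[, end_bp := start_bp + as.integer(glen) - 1L]
  # decoy genes: uniform, rejected on overlap with anything already placed
  occupied <- data.table::copy(path_genes[, .(chrom, start_bp, end_bp)])
  decoys <- vector("list", n_decoy)
  n_done <- 0L
  attempts <- 0L
  while (n_done < n_decoy) {
    attempts <- attempts + 1L
    if (attempts > 50L * n_decoy) {
      stop("make_network: configuration error - decoy placement unsatisfiable")
    }
    ch <- sample(names(chrom_lengths), 1)
    len <- as.integer(round(stats::runif(1, 0.5, 2.5) * glen))
    s <- as.integer(floor(stats::runif(1, 1, chrom_lengths[[ch]] - len)))
    e <- s + len - 1L
    clash <- occupied[chrom == ch & start_bp <= e & end_bp >= s]
    if (nrow(clash)) next
    n_done <- n_done + 1L
    decoys[[n_done]] <- data.table::data.table(chrom = ch, start_bp = s,
                                               end_bp = e)
    occupied <- data.table::rbindlist(list(occupied, decoys[[n_done]]))
  }
  decoys <- data.table::rbindlist(decoys)
  decoys[, gene_id := sprintf("DECOY%04d", .I)]
  decoys[, gene_type := sample(c("general", "unknown"), .N, replace = TRUE,
                               prob = c(0.85, 0.15))]
  all_genes <- data.table::rbindlist(list(path_genes, decoys),
                                     use.names = TRUE)
  data.table::setorder(all_genes, chrom, start_bp)
  # pathway membership / relevant metabolites drive downstream annotation:
  # enzymes are relevant to metabolites adjacent to their reaction edges,
  # transporters to their cargo, TFs to their entry node.
  rel <- stats::setNames(pg$attach, pg$gene_id)
  pw <- stats::setNames(paste0("pw_", pg$gene_type), pg$gene_id)
  genes <- gene_table(
    gene_id = all_genes$gene_id, chrom = all_genes$chrom,
    start_bp = all_genes$start_bp, end_bp = all_genes$end_bp,
    gene_type = all_genes$gene_type,
    pathways = lapply(all_genes$gene_id, function(g) {
      if (g %in% names(pw)) pw[[g]]
      else if (startsWith(g, "DECOY")) "pw_general" else character()
    }),
    relevant_metabolites = lapply(all_genes$gene_id, function(g) {
      if (g %in% names(rel)) rel[[g]] else character()
    })
  )
  list(network = network, genes = genes)
}
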