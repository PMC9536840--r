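# Readers/writers for the tabular and interval formats the pipeline consumes.
# On disk, interval files are BED-dialect (0-based half-open); in memory all
# coordinates are 1-based inclusive, matching base-pair distance arithmetic.

.mandatory_sumstat_cols <- c("variant_id", "chrom", "pos_bp",
                             "effect_allele", "other_allele")

.alias_map <- list(
  variant_id = c("variant_id", "snp", "id", "rsid"),
  chrom = c("chrom", "chr", "chromosome"),
  pos_bp = c("pos_bp", "bp", "pos", "position"),
  cm = c("cm", "cm_pos", "genetic_dist"),
  effect_allele = c("effect_allele", "a1", "allele1"),
  other_allele = c("other_allele", "a2", "allele2")
)

#' Construct a validated summary-statistics table
#'
#' @param dt data.frame/data.table with canonical columns `variant_id`,
#'   `chrom`, `pos_bp`, `cm`, `effect_allele`, `other_allele` and one
#'   `beta_<m>`, `se_<m>`, `p_<m>` triplet per metabolite.
#' @param metabolites character vector of metabolite names.
#' @return A `sumstats` data.table.
#' @export
sumstats_table <- function(dt, metabolites) {
  dt <- data.table::as.data.table(dt)
  need <- c(.mandatory_sumstat_cols, "cm",
            paste0(rep(c("beta_", "se_", "p_"), length(metabolites)),
                   rep(metabolites, each = 3)))
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("sumstats format error: missing column(s) ",
         paste(miss, collapse = ", "))
  }
  data.table::setcolorder(dt, need)
  data.table::setattr(dt, "metabolites", metabolites)
  data.table::setattr(dt, "class", c("sumstats", class(dt)))
  dt
}

#' Metabolites covered by a sumstats or leads table
#' @param x a `sumstats` or `leads` table.
#' @return character vector of metabolite names.
#' @export
metabolites <- function(x) attr(x, "metabolites")

#' Read GWAS summary statistics for a panel of metabolites
#'
#' Accepts whitespace/tab-delimited files with a header. Column aliases are
#' accepted for the variant fields (`SNP`, `CHR`, `BP`, `A1`, `A2`, ...) and
#' per-trait triplets may be named `BETA_<met>`/`SE_<met>` with `P_<met>` or
#' `P_BOLT_LMM_<met>`. Rows violating the table invariants (se > 0,
#' p in (0, 1], pos >= 1, complete triplets, unique variant ids) are rejected
#' and the rejection count is logged to standard error.
#'
#' If no cM column is supplied, positions are mapped at 1 cM/Mb.
#'
#' @param path file path.
#' @param metabolite_names metabolites whose triplets must be present.
#' @return A `sumstats` data.table; attribute `n_rejected` carries the number
#'   of dropped rows.
#' @export
read_sumstats <- function(path, metabolite_names) {
  raw <- data.table::fread(path, header = TRUE)
  lc <- tolower(names(raw))
  out <- data.table::data.table(.row = seq_len(nrow(raw)))
  for (fld in names(.alias_map)) {
    hit <- which(lc %in% .alias_map[[fld]])
    if (length(hit)) out[[fld]] <- raw[[hit[1]]]
  }
  miss <- setdiff(.mandatory_sumstat_cols, names(out))
  if (length(miss)) {
    stop("sumstats format error: missing column(s) ",
         paste(miss, collapse = ", "))
  }
  if (is.null(out$cm)) out$cm <- out$pos_bp * 1e-6
  for (m in metabolite_names) {
    for (kind in c("beta", "se", "p")) {
      pats <- paste0(tolower(c(kind, if (kind == "p") "p_bolt_lmm")), "_",
                     tolower(m))
      hit <- which(lc %in% pats)
      if (!length(hit)) {
        stop("sumstats format error: missing column ", kind, "_", m)
      }
      v <- raw[[hit[1]]]
      if (!is.numeric(v)) {
        num <- suppressWarnings(as.numeric(v))
        bad <- which(!is.na(v) & is.na(num))
        if (length(bad)) {
          stop(sprintf("sumstats row error: non-numeric %s_%s at line %d",
                       kind, m, bad[1] + 1L))
        }
        v <- num
      }
      out[[paste0(kind, "_", m)]] <- v
    }
  }
  ok <- out$pos_bp >= 1 & !is.na(out$pos_bp)
  for (m in metabolite_names) {
    b <- out[[paste0("beta_", m)]]
    s <- out[[paste0("se_", m)]]
    p <- out[[paste0("p_", m)]]
    ok <- ok & !is.na(b) & !is.na(s) & !is.na(p) & s > 0 & p > 0 & p <= 1
  }
  ok[is.na(ok)] <- FALSE
  ok <- ok & !duplicated(out$variant_id)
  n_rej <- sum(!ok)
  if (n_rej > 0) {
    met_log(sprintf("read_sumstats: rejected %d of %d rows failing invariants",
                    n_rej, nrow(out)))
  }
  out <- out[ok]
  out[, .row := NULL]
  ss <- sumstats_table(out, metabolite_names)
  data.table::setattr(ss, "n_rejected", n_rej)
  ss
}

#' @rdname write_table
#' @export
write_sumstats <- function(obj, path) {
  data.table::fwrite(data.table::as.data.table(obj), path, sep = "\t")
  invisible(path)
}

#' Construct a gene annotation table
#'
#' @param gene_id,chrom,start_bp,end_bp,gene_type vectors of equal length;
#'   coordinates 1-based inclusive; `gene_type` one of `enzyme`,
#'   `transporter`, `tf`, `general`, `unknown`.
#' @param pathways,relevant_metabolites list columns of character vectors
#'   (pathway ids / metabolite ids per gene).
#' @return A `gene_table` data.table.
#' @export
gene_table <- function(gene_id, chrom, start_bp, end_bp, gene_type,
                       pathways = NULL, relevant_metabolites = NULL) {
  n <- length(gene_id)
  if (is.null(pathways)) pathways <- rep(list(character()), n)
  if (is.null(relevant_metabolites)) {
    relevant_metabolites <- rep(list(character()), n)
  }
  stopifnot(length(unique(gene_id)) == n)
  if (any(start_bp > end_bp)) stop("gene_table: start_bp > end_bp")
  bad <- setdiff(gene_type, c("enzyme", "transporter", "tf", "general",
                              "unknown"))
  if (length(bad)) stop("gene_table: unknown gene_type ", bad[1])
  dt <- data.table::data.table(
    gene_id = gene_id, chrom = chrom,
    start_bp = as.integer(start_bp), end_bp = as.integer(end_bp),
    gene_type = gene_type, pathways = pathways,
    relevant_metabolites = relevant_metabolites
  )
  data.table::setattr(dt, "class", c("gene_table", class(dt)))
  dt
}

.collapse_set <- function(x) {
  vapply(x, function(v) if (length(v)) paste(v, collapse = ",") else ".",
         character(1))
}
.split_set <- function(x) {
  lapply(as.character(x), function(v) {
    if (is.na(v) || v == "." || v == "") character() else
      strsplit(v, ",", fixed = TRUE)[[1]]
  })
}

#' Read gene intervals from a BED-dialect file
#'
#' Expects headerless tab-separated columns: chrom, start (0-based),
#' end (half-open), gene_id, gene_type, pathways, relevant_metabolites, the
#' last two comma-separated with `.` for the empty set. Trailing columns may
#' be omitted (`gene_type` then defaults to `unknown`). Coordinates are
#' converted losslessly to the in-memory 1-based inclusive convention.
#'
#' @param path file path.
#' @return A `gene_table`.
#' @export
read_genes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 4) stop("gene BED format error: need at least 4 columns")
  data.table::setnames(dt, seq_len(min(ncol(dt), 7)),
                       c("chrom", "start", "end", "gene_id", "gene_type",
                         "pathways", "relevant_metabolites")[
                           seq_len(min(ncol(dt), 7))])
  if (any(dt$start >= dt$end)) {
    stop("gene BED format error: start >= end on disk")
  }
  gene_table(
    gene_id = as.character(dt$gene_id), chrom = as.character(dt$chrom),
    start_bp = dt$start + 1L, end_bp = dt$end,
    gene_type = if ("gene_type" %in% names(dt)) as.character(dt$gene_type)
                else rep("unknown", nrow(dt)),
    pathways = if ("pathways" %in% names(dt)) .split_set(dt$pathways),
    relevant_metabolites = if ("relevant_metabolites" %in% names(dt))
      .split_set(dt$relevant_metabolites)
  )
}

#' @rdname write_table
#' @export
write_genes <- function(obj, path) {
  out <- data.table::data.table(
    chrom = obj$chrom, start = obj$start_bp - 1L, end = obj$end_bp,
    gene_id = obj$gene_id, gene_type = obj$gene_type,
    pathways = .collapse_set(obj$pathways),
    relevant_metabolites = .collapse_set(obj$relevant_metabolites)
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read LD-block (or other plain) intervals from a BED file
#'
#' @param path headerless BED: chrom, start (0-based), end (half-open),
#'   optional name.
#' @return data.table with `chrom`, `start_bp`, `end_bp` (1-based inclusive)
#'   and `block_id`.
#' @export
read_blocks <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (any(dt$V2 >= dt$V3)) stop("block BED format error: start >= end on disk")
  data.table::data.table(
    chrom = as.character(dt$V1), start_bp = dt$V2 + 1L, end_bp = dt$V3,
    block_id = if (ncol(dt) >= 4) as.character(dt$V4)
               else sprintf("block%04d", seq_len(nrow(dt)))
  )
}

#' @rdname write_table
#' @export
write_blocks <- function(obj, path) {
  out <- data.table::data.table(obj$chrom, obj$start_bp - 1L, obj$end_bp,
                                obj$block_id)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a pipeline table to disk
#'
#' Dispatches on the object class: `sumstats` and generic data.frames go to
#' TSV; `gene_table` and block tables go to BED-dialect files with 0-based
#' half-open coordinates.
#'
#' @param obj table to write.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path) UseMethod("write_table")

#' @export
write_table.sumstats <- function(obj, path) write_sumstats(obj, path)

#' @export
write_table.gene_table <- function(obj, path) write_genes(obj, path)

#' @export
write_table.default <- function(obj, path) {
  dt <- data.table::as.data.table(obj)
  for (col in names(dt)) {
    if (is.list(dt[[col]])) dt[[col]] <- .collapse_set(dt[[col]])
  }
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read/write a metabolic reaction network as JSON
#'
#' @param path file path.
#' @return For `read_network`, a `met_network` (see [met_network()]).
#' @export
read_network <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- data.table::as.data.table(j$edges)
  met_network(
    nodes = data.table::as.data.table(j$nodes),
    edges = data.table::data.table(
      substrate = edges$substrate, product = edges$product,
      enzymes = if (is.list(edges$enzymes)) edges$enzymes
                else as.list(edges$enzymes),
      reversible = edges$reversible
    ),
    transporters = lapply(j$transporters, unlist),
    regulators = data.table::as.data.table(j$regulators)
  )
}

#' @rdname read_network
#' @param network a `met_network` to serialize.
#' @export
write_network <- function(network, path) {
  jsonlite::write_json(
    list(
      nodes = network$nodes,
      edges = data.frame(
        substrate = network$edges$substrate,
        product = network$edges$product,
        enzymes = I(network$edges$enzymes),
        reversible = network$edges$reversible
      ),
      transporters = network$transporters,
      regulators = network$regulators
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read/write a run configuration as YAML
#' @param path file path.
#' @return For `read_config`, a `met_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- lapply(vals, function(v) {
    if (is.list(v) && length(v) && all(lengths(v) == 1)) unlist(v) else v
  })
  do.call(met_config, vals)
}

#' @rdname read_config
#' @param config a `met_config`.
#' @export
write_config <- function(config, path) {
  vals <- lapply(unclass(config), function(v) {
    if (is.atomic(v) && !is.null(names(v))) as.list(v) else v
  })
  yaml::write_yaml(vals, path)
  invisible(path)
}
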