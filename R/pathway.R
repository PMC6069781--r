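#' Gene-ordered pathway
#'
#' A pathway is a set of genes carrying their genomic order (integer ranks on
#' the merged one-line genome sequence) together with the metabolic-network
#' subgraph induced on its members.  The gene order is the organism-specific
#' order relation g1 <= g2 <= ... <= gn; members are stored sorted by rank.
#'
#' @param pathway_id pathway identifier (e.g. `"path:eco00010"`).
#' @param gene_ids character vector of member gene ids (no duplicates).
#' @param ranks named integer vector (or plain vector parallel to
#'   `gene_ids`) of genomic positions; must be unique.
#' @param network the global [metabolic_network] from which the member
#'   subgraph is induced (members absent from it become isolated nodes).
#'
#' @return object of class `gene_ordered_pathway` with fields `pathway_id`,
#'   `members` (rank-sorted), `ranks` (named), `subgraph`.
#' @export
gene_ordered_pathway <- function(pathway_id, gene_ids, ranks, network) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids))
    stop_mora("pathway %s has duplicate members", pathway_id)
  if (is.null(names(ranks))) names(ranks) <- gene_ids
  ranks <- ranks[gene_ids]
  if (anyNA(ranks))
    stop_mora("pathway %s: missing rank for some member", pathway_id)
  if (anyDuplicated(ranks))
    stop_mora("pathway %s: ranks must be unique", pathway_id)
  ord <- order(ranks)
  members <- gene_ids[ord]
  structure(list(pathway_id = pathway_id,
                 members = members,
                 ranks = stats::setNames(as.integer(ranks[ord]), members),
                 subgraph = induced_network(network, members)),
            class = "gene_ordered_pathway")
}

#' @export
print.gene_ordered_pathway <- function(x, ...) {
  cat(sprintf("<gene_ordered_pathway> %s: %d genes, %d arcs\n",
              x$pathway_id, length(x$members),
              igraph::ecount(x$subgraph$graph)))
  invisible(x)
}

#' Read pathway membership with gene order from TSV
#'
#' Columns: `pathway_id`, `gene_id`, `rank` (integer genomic position).
#'
#' @param path TSV file.
#' @param network the global [metabolic_network].
#' @return named list of [gene_ordered_pathway] objects.
#' @export
read_pathways <- function(path, network) {
  raw <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("pathway_id", "gene_id", "rank")
  if (!all(need %in% names(raw)))
    stop_mora("pathway TSV must have columns %s", paste(need, collapse = ", "))
  out <- lapply(split(raw, raw$pathway_id), function(d) {
    gene_ordered_pathway(d$pathway_id[[1L]], d$gene_id,
                         stats::setNames(as.integer(d$rank), d$gene_id),
                         network)
  })
  out[order(names(out))]
}

#' Operon membership map
#'
#' @param x named list `operon_id -> character vector of gene ids` or a
#'   data.frame with columns `operon_id`, `gene_id`.
#' @return object of class `operon_map` (named list); errors if a gene
#'   belongs to more than one operon.
#' @export
operon_map <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("operon_id", "gene_id") %in% names(x)))
      stop_mora("operon table must have columns operon_id, gene_id")
    x <- lapply(split(as.character(x$gene_id), x$operon_id), unique)
  }
  all_genes <- unlist(x, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    dup <- unique(all_genes[duplicated(all_genes)])
    stop_mora("gene(s) in more than one operon: %s",
              paste(dup, collapse = ", "))
  }
  structure(x, class = "operon_map")
}

#' Read an operon map from TSV (columns `operon_id`, `gene_id`)
#' @param path TSV file.
#' @return an [operon_map].
#' @export
read_operons <- function(path) {
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  operon_map(raw)
}

#' Discretized multi-omic pattern
#'
#' A `binary_pattern` is the array of discretization levels of one pathway's
#' multi-omic values arranged by gene order (the "mov" of the model).  Levels
#' live in Sigma = {0, ..., n_levels - 1}; the default two-level field is the
#' binary high/low discretization.
#'
#' @param values integer vector of levels in `0:(n_levels-1)`.
#' @param positions character vector of gene ids (or synthetic ids for
#'   inserted extension nodes), parallel to `values`.
#' @param n_levels number of discretization levels (N >= 2).
#' @return object of class `binary_pattern`.
#' @export
binary_pattern <- function(values, positions = NULL, n_levels = 2L) {
  values <- as.integer(values)
  if (!length(values)) stop_mora("pattern must have at least 1 element")
  if (is.null(positions)) positions <- paste0("e", seq_along(values))
  positions <- as.character(positions)
  if (length(positions) != length(values))
    stop_mora("values and positions must have equal length")
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop_mora("n_levels must be >= 2")
  if (any(values < 0L | values >= n_levels))
    stop_mora("pattern values must lie in 0..%d", n_levels - 1L)
  structure(list(values = values, positions = positions,
                 n_levels = n_levels),
            class = "binary_pattern")
}

#' @export
print.binary_pattern <- function(x, ...) {
  cat(sprintf("<binary_pattern> N=%d: %s\n", x$n_levels,
              paste(x$values, collapse = "-")))
  invisible(x)
}

#' @export
length.binary_pattern <- function(x) length(x$values)
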