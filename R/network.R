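#' Directed protein-centric metabolic network
#'
#' Wraps a directed [igraph::igraph] graph whose nodes are gene/protein
#' identifiers and whose arcs are enzymatic reactions.  Reversible reactions
#' are stored as two opposite arcs; self-loops are disallowed.  The average
#' path length (APL) of the undirected view is computed lazily and cached.
#'
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `reversible` (0/1 or logical; default irreversible).  Each reversible row
#'   expands into two arcs.  Self-loop rows are dropped with a warning.
#' @param nodes optional character vector of node ids; ids appearing only
#'   here become isolated nodes.
#'
#' @return An object of class `metabolic_network`: a list with elements
#'   `graph` (directed igraph) and `apl` (cached APL or `NULL`).
#' @export
metabolic_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(edges)))
    stop_mora("edges must have columns 'from' and 'to'")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  rev <- if ("reversible" %in% names(edges)) {
    as.logical(as.integer(edges$reversible))
  } else rep(FALSE, nrow(edges))
  loop <- edges$from == edges$to
  if (any(loop)) {
    warn_mora("dropped %d self-loop edge(s)", sum(loop))
    edges <- edges[!loop, , drop = FALSE]
    rev <- rev[!loop]
  }
  from <- c(edges$from, edges$to[rev])
  to <- c(edges$to, edges$from[rev])
  ids <- unique(c(from, to, as.character(nodes)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE, vertices = ids)
  structure(list(graph = g, apl = NULL), class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d nodes, %d arcs%s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              if (is.null(x$apl)) "" else sprintf(", APL %.3f", x$apl)))
  invisible(x)
}

#' Node ids of a metabolic network
#' @param net a [metabolic_network].
#' @return character vector of node ids.
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' Average path length of the undirected network view
#'
#' Mean undirected shortest-path length over all connected unordered node
#' pairs; pairs falling in different components are excluded so the APL stays
#' finite on fragmented networks.
#'
#' @param net a [metabolic_network] with at least 2 nodes.
#' @return positive scalar.
#' @export
average_path_length <- function(net) {
  if (!is.null(net$apl)) return(net$apl)
  g <- net$graph
  if (igraph::vcount(g) < 2L)
    stop_mora("average_path_length needs at least 2 nodes")
  apl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  if (!is.finite(apl) || is.nan(apl))
    stop_mora("network has no connected node pair")
  apl
}

#' Cache the APL on a network object
#' @param net a [metabolic_network].
#' @return the network with its `apl` field filled.
#' @export
with_apl <- function(net) {
  net$apl <- average_path_length(net)
  net
}

#' Read a metabolic network
#'
#' @param path input file.
#' @param dialect `"edgelist"` for a TSV with columns `from`, `to`,
#'   `reversible` (0/1), or `"graphml"` for GraphML as written by
#'   [write_network()].
#' @return a [metabolic_network].
#' @export
read_network <- function(path, dialect = c("edgelist", "graphml")) {
  dialect <- match.arg(dialect)
  if (dialect == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (!igraph::is_directed(g)) g <- igraph::as_directed(g, mode = "arbitrary")
    net <- structure(list(graph = g, apl = NULL), class = "metabolic_network")
    return(net)
  }
  raw <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 3L)
    stop_mora("edge list must have columns from, to, reversible")
  names(raw)[1:3] <- c("from", "to", "reversible")
  metabolic_network(raw[, 1:3])
}

#' Write a metabolic network
#'
#' The edge-list dialect writes one row per stored arc (`reversible = 0`),
#' so a write/read round trip preserves the arc multiset exactly; isolated
#' nodes are only preserved by the GraphML dialect.
#'
#' @param net a [metabolic_network].
#' @param path output file.
#' @inheritParams read_network
#' @return invisibly, `path`.
#' @export
write_network <- function(net, path, dialect = c("edgelist", "graphml")) {
  dialect <- match.arg(dialect)
  if (dialect == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_data_frame(net$graph, what = "edges")[, c("from", "to")]
  el$reversible <- 0L
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Induced subgraph as a metabolic_network; members absent from the network
# become isolated nodes so pattern positions stay mappable.
#' @noRd
induced_network <- function(net, members) {
  present <- intersect(members, network_nodes(net))
  g <- igraph::induced_subgraph(net$graph, present)
  missing <- setdiff(members, present)
  if (length(missing)) g <- igraph::add_vertices(g, length(missing),
                                                 name = missing)
  structure(list(graph = g, apl = NULL), class = "metabolic_network")
}
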