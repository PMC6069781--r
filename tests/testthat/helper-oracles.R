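# Independent brute-force oracles, deliberately not using igraph, against
# which the package implementations are checked on small instances.

# undirected adjacency list from a data.frame of arcs (from, to)
oracle_adjacency <- function(edges) {
  adj <- list()
  for (k in seq_len(nrow(edges))) {
    u <- edges$from[k]; v <- edges$to[k]
    if (u == v) next
    adj[[u]] <- union(adj[[u]], v)
    adj[[v]] <- union(adj[[v]], u)
  }
  adj
}

# all simple paths (node-id vectors) from a to b with <= maxlen edges
oracle_simple_paths <- function(adj, a, b, maxlen) {
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == b && length(path) > 1L) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) - 1L >= maxlen) return(invisible())
    for (nb in adj[[last]]) {
      if (!(nb %in% path)) walk(c(path, nb))
    }
  }
  if (!is.null(adj[[a]])) walk(a)
  out
}

# reciprocal-influence weights recomputed from first principles
oracle_mora <- function(values, mapping, edges, apl_ceiling,
                        wraparound = TRUE) {
  n <- length(values)
  adj <- oracle_adjacency(edges)
  couples <- cbind(seq_len(n - 1L), seq.int(2L, n))
  if (wraparound && n > 2L) couples <- rbind(couples, c(n, 1L))
  infl <- numeric(n)
  for (k in seq_len(nrow(couples))) {
    a <- mapping[couples[k, 1L]]; b <- mapping[couples[k, 2L]]
    if (is.na(a) || is.na(b) || a == b) next
    for (p in oracle_simple_paths(adj, a, b, apl_ceiling)) {
      w <- 1 / (length(p) - 1L)
      for (v in p) {
        z <- which(mapping == v)
        infl[z] <- infl[z] + w
      }
    }
  }
  infl
}

# mean shortest-path length over connected unordered pairs, by
# Floyd-Warshall on the undirected adjacency matrix
oracle_apl <- function(edges, nodes) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (k in seq_len(nrow(edges))) {
    u <- edges$from[k]; v <- edges$to[k]
    d[u, v] <- d[v, u] <- 1
  }
  for (m in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, m] + d[m, j] < d[i, j]) d[i, j] <- d[i, m] + d[m, j]
  up <- d[upper.tri(d)]
  mean(up[is.finite(up)])
}

# arcs of a metabolic_network as a data.frame (via the public writer)
net_arcs <- function(net) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write_network(net, f)
  utils::read.delim(f, stringsAsFactors = FALSE)
}

# convenience: pathway + mls over n chain/complete/etc nodes
fixture_mls <- function(net, values, ids = NULL) {
  ids <- ids %||% network_nodes(net)
  ids <- ids[seq_along(values)]
  pw <- gene_ordered_pathway("path:test", ids,
                             stats::setNames(seq_along(ids), ids), net)
  build_mls(pw, binary_pattern(values, ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive matrix of all 2^l binary patterns of length l
all_binary_patterns <- function(l) {
  as.matrix(expand.grid(rep(list(0:1), l)))
}

# small omics TSV writer for reader tests
write_omics_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
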