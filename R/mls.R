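#' Multi-layered structure (MLS)
#'
#' Couples a gene-ordered pathway graph with its discretized multi-omic
#' pattern through a position-to-node mapping.  The mapping records, for each
#' pattern position, the pathway node it addresses; after operon compression
#' a position may represent a set of merged nodes (kept in `merged`), with
#' the first member in gene order acting as representative for the path
#' search.
#'
#' @param pathway a [gene_ordered_pathway].
#' @param pattern a [binary_pattern] whose positions are pathway members in
#'   gene (rank) order.
#' @param setup one of `"plain"`, `"opc"` (operon compression), `"ext"`
#'   (path extension), `"opc+ext"`.
#' @param condition condition label (`"steady"`, `"avg"`, or a treatment id).
#' @return object of class `mls` with fields `pathway`, `pattern`,
#'   `mapping` (character vector, node per position), `merged` (list of node
#'   sets per position), `setup`, `condition`.
#' @export
build_mls <- function(pathway, pattern, setup = "plain",
                      condition = "steady") {
  stopifnot(inherits(pathway, "gene_ordered_pathway"),
            inherits(pattern, "binary_pattern"))
  pos <- pattern$positions
  missing <- setdiff(pos, pathway$members)
  if (length(missing))
    stop_mora("pattern position(s) not in pathway %s: %s",
              pathway$pathway_id, paste(missing, collapse = ", "))
  rk <- pathway$ranks[pos]
  if (is.unsorted(rk, strictly = TRUE))
    stop_mora("pattern positions must follow the gene order of pathway %s",
              pathway$pathway_id)
  structure(list(pathway = pathway, pattern = pattern,
                 mapping = pos,
                 merged = as.list(pos),
                 setup = setup, condition = condition),
            class = "mls")
}

#' @export
print.mls <- function(x, ...) {
  cat(sprintf("<mls> %s [%s, %s]: pattern %s\n", x$pathway$pathway_id,
              x$setup, x$condition, paste(x$pattern$values, collapse = "-")))
  invisible(x)
}

#' Operon compression of an MLS
#'
#' Each maximal run of pattern elements whose genes belong to the same
#' operon is replaced by a single element carrying the run's most frequent
#' (modal) value; an even tie takes the value of the first element in gene
#' order, with a warning.  The gene order of untouched elements is
#' unaltered.  The compressed element represents all merged nodes (its
#' `merged` set), with the first member as representative position id.
#' Operon members that are not contiguous in the pattern raise an error.
#'
#' @param mls an [build_mls()] object.
#' @param operons an [operon_map].
#' @return the compressed `mls`; idempotent on its own output.
#' @export
operon_compression <- function(mls, operons) {
  stopifnot(inherits(mls, "mls"), inherits(operons, "operon_map"))
  pos <- mls$pattern$positions
  gene2op <- stats::setNames(
    rep(names(operons), lengths(operons)),
    unlist(operons, use.names = FALSE))
  op <- unname(gene2op[pos])  # NA for genes outside any operon

  # run ids: consecutive equal non-NA operon ids form one run
  run <- integer(length(pos))
  rid <- 1L
  run[1L] <- rid
  for (j in seq_along(pos)[-1L]) {
    same <- !is.na(op[j]) && !is.na(op[j - 1L]) && op[j] == op[j - 1L]
    if (!same) rid <- rid + 1L
    run[j] <- rid
  }
  # contiguity check: every operon id present must form exactly one run
  present <- !is.na(op)
  if (any(present)) {
    per_op <- tapply(run[present], op[present], function(r) length(unique(r)))
    bad <- names(per_op)[per_op > 1L]
    if (length(bad))
      stop_mora("operon(s) %s have non-contiguous members in the pattern",
                paste(bad, collapse = ", "))
  }

  vals <- mls$pattern$values
  new_vals <- integer(0)
  new_pos <- character(0)
  new_map <- character(0)
  new_merged <- list()
  for (r in unique(run)) {
    j <- which(run == r)
    if (length(j) == 1L) {
      new_vals <- c(new_vals, vals[j])
      new_pos <- c(new_pos, pos[j])
      new_map <- c(new_map, mls$mapping[j])
      new_merged <- c(new_merged, mls$merged[j])
    } else {
      tab <- table(vals[j])
      if (sum(tab == max(tab)) > 1L)
        warn_mora("operon run at %s: value tie, taking first element's value",
                  pos[j[1L]])
      new_vals <- c(new_vals, modal_value(vals[j]))
      new_pos <- c(new_pos, pos[j[1L]])
      new_map <- c(new_map, mls$mapping[j[1L]])
      new_merged <- c(new_merged, list(unique(unlist(mls$merged[j]))))
    }
  }
  mls$pattern <- binary_pattern(new_vals, new_pos, mls$pattern$n_levels)
  mls$mapping <- new_map
  mls$merged <- new_merged
  mls$setup <- if (identical(mls$setup, "plain")) "opc" else mls$setup
  mls
}

#' Oscillation-guided path extension of an MLS
#'
#' For every adjacent pattern pair that does not alternate
#' (`|e_j - e_{j+1}| = 0`), searches the global metabolic network (undirected
#' view) for alternative simple paths between the two mapped nodes that
#' leave the direct connection: edge length at least 2, at most
#' `apl_ceiling + 1`.  Among the minimum-length candidates the path whose
#' inserted value sequence (endpoint values plus the intermediate nodes'
#' organism-wide binary values) maximizes the alternation score is chosen;
#' score ties fall to the lexicographically smallest node-id sequence, with
#' a warning.  The intermediate nodes' values are inserted between the pair,
#' the nodes and traversed reactions join the pathway subgraph, and pairs
#' with no qualifying candidate are left unchanged.  Candidates containing a
#' node without a discretized value are discarded with a warning.
#'
#' @param mls an [build_mls()] object.
#' @param global_net the global [metabolic_network].
#' @param global_values named 0/1 vector from [global_binary_values()]
#'   (organism-wide discretization for the MLS condition).
#' @param config a [mora_config()]; its `apl_ceiling` bounds the detour.
#' @return the extended `mls`; removing the inserted elements recovers the
#'   original pattern exactly.
#' @export
path_extension <- function(mls, global_net, global_values, config) {
  stopifnot(inherits(mls, "mls"), inherits(global_net, "metabolic_network"))
  vals <- mls$pattern$values
  n <- length(vals)
  if (n < 2L) return(mls)
  gu <- igraph::as_undirected(global_net$graph, mode = "collapse")
  max_len <- config$apl_ceiling + 1L
  nodes_g <- igraph::V(gu)$name

  insert_after <- vector("list", n)  # per gap j: list(values, nodes)
  for (j in seq_len(n - 1L)) {
    if (vals[j] != vals[j + 1L]) next
    a <- mls$mapping[j]; b <- mls$mapping[j + 1L]
    if (is.na(a) || is.na(b) || !(a %in% nodes_g) || !(b %in% nodes_g) ||
        a == b) next
    paths <- igraph::all_simple_paths(gu, a, to = b, cutoff = max_len)
    cand <- Filter(function(p) length(p) >= 3L, paths)  # >= 2 edges
    if (!length(cand)) next
    # value each candidate; discard those with unvalued intermediates
    scored <- lapply(cand, function(p) {
      ids <- names(p)
      mid <- ids[-c(1L, length(ids))]
      if (!all(mid %in% names(global_values))) return(NULL)
      seqv <- c(vals[j], unname(global_values[mid]), vals[j + 1L])
      list(ids = ids, mid = mid, len = length(ids) - 1L,
           score = sum(abs(diff(seqv))) / mls$pattern$n_levels)
    })
    dropped <- sum(vapply(scored, is.null, logical(1)))
    if (dropped)
      warn_mora("pathway %s gap %d: discarded %d path(s) with unvalued nodes",
                mls$pathway$pathway_id, j, dropped)
    scored <- Filter(Negate(is.null), scored)
    if (!length(scored)) next
    lens <- vapply(scored, `[[`, numeric(1), "len")
    scored <- scored[lens == min(lens)]
    scores <- vapply(scored, `[[`, numeric(1), "score")
    best <- which(scores == max(scores))
    if (length(best) > 1L) {
      keys <- vapply(scored[best], function(s) paste(s$ids, collapse = "\r"),
                     character(1))
      warn_mora("pathway %s gap %d: alternation tie, taking first path in id order",
                mls$pathway$pathway_id, j)
      best <- best[order(keys)]
    }
    ch <- scored[[best[[1L]]]]
    insert_after[[j]] <- list(values = unname(global_values[ch$mid]),
                              nodes = ch$mid, path_ids = ch$ids)
  }

  if (all(vapply(insert_after, is.null, logical(1)))) return(mls)

  new_vals <- integer(0); new_pos <- character(0)
  new_map <- character(0); new_merged <- list()
  inserted <- logical(0)
  add_nodes <- character(0); add_edges <- NULL
  for (j in seq_len(n)) {
    new_vals <- c(new_vals, vals[j])
    new_pos <- c(new_pos, mls$pattern$positions[j])
    new_map <- c(new_map, mls$mapping[j])
    new_merged <- c(new_merged, mls$merged[j])
    inserted <- c(inserted, FALSE)
    ins <- insert_after[[j]]
    if (!is.null(ins)) {
      new_vals <- c(new_vals, ins$values)
      new_pos <- c(new_pos, ins$nodes)
      new_map <- c(new_map, ins$nodes)
      new_merged <- c(new_merged, as.list(ins$nodes))
      inserted <- c(inserted, rep(TRUE, length(ins$nodes)))
      add_nodes <- union(add_nodes, ins$nodes)
      steps <- cbind(ins$path_ids[-length(ins$path_ids)], ins$path_ids[-1L])
      add_edges <- rbind(add_edges, steps)
    }
  }

  sg <- mls$pathway$subgraph$graph
  newv <- setdiff(add_nodes, igraph::V(sg)$name)
  if (length(newv)) sg <- igraph::add_vertices(sg, length(newv), name = newv)
  if (!is.null(add_edges)) {
    # carry over the actual arcs of the global network along each step,
    # skipping arcs the subgraph already holds
    gel <- igraph::as_edgelist(global_net$graph, names = TRUE)
    want <- NULL
    for (k in seq_len(nrow(add_edges))) {
      u <- add_edges[k, 1L]; v <- add_edges[k, 2L]
      hit <- (gel[, 1L] == u & gel[, 2L] == v) |
             (gel[, 1L] == v & gel[, 2L] == u)
      want <- rbind(want, gel[hit, , drop = FALSE])
    }
    want <- unique(want)
    sel <- igraph::as_edgelist(sg, names = TRUE)
    have <- paste(sel[, 1L], sel[, 2L])
    new <- want[!(paste(want[, 1L], want[, 2L]) %in% have), , drop = FALSE]
    if (nrow(new)) sg <- igraph::add_edges(sg, as.vector(t(new)))
  }
  mls$pathway$subgraph <- structure(list(graph = sg, apl = NULL),
                                    class = "metabolic_network")
  mls$pattern <- binary_pattern(new_vals, new_pos, mls$pattern$n_levels)
  mls$mapping <- new_map
  mls$merged <- new_merged
  mls$inserted <- inserted
  mls$setup <- if (identical(mls$setup, "opc")) "opc+ext" else "ext"
  mls
}

#' Node labels implied by an MLS pattern
#'
#' Maps every node represented by a pattern position (including merged
#' operon members, which all carry their run's compressed value) to its
#' binary value, for dyad counting on the subgraph.
#'
#' @param mls an `mls`.
#' @return named integer vector of 0/1 labels.
#' @export
mls_node_labels <- function(mls) {
  lab <- integer(0)
  for (j in seq_along(mls$merged)) {
    nodes <- mls$merged[[j]]
    lab[nodes[!(nodes %in% names(lab))]] <- mls$pattern$values[j]
  }
  lab
}
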