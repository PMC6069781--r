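#' MORA search configuration
#'
#' The reciprocal-influence search credits a couple of sequence-adjacent
#' multi-omics for every simple path between their mapped pathway nodes of
#' edge length psi in `1..apl_ceiling`, with weight `1/psi` (a direct
#' reaction contributes weight 1).  The ceiling is the rounded-up average
#' path length of the *global* metabolic network, which bounds how far an
#' influence propagates.
#'
#' @param apl_ceiling integer >= 1; typically `ceiling(average_path_length(net))`
#'   of the global network.
#' @param include_wraparound also evaluate the (last, first) couple
#'   (default `TRUE`).
#' @param undirected_search run the path search on the undirected view of
#'   the pathway subgraph (default `TRUE`, matching the undirected
#'   shortest-path definition of a strong relationship).
#' @return object of class `mora_config`; the sequence adjacency distance
#'   `delta` is fixed at 2 (adjacent positions).
#' @export
mora_config <- function(apl_ceiling, include_wraparound = TRUE,
                        undirected_search = TRUE) {
  apl_ceiling <- as.integer(ceiling(apl_ceiling))
  if (!is_count(apl_ceiling) || apl_ceiling < 1L)
    stop_mora("apl_ceiling must be a positive integer")
  structure(list(apl_ceiling = apl_ceiling, delta = 2L,
                 include_wraparound = isTRUE(include_wraparound),
                 undirected_search = isTRUE(undirected_search)),
            class = "mora_config")
}

#' MORA: reciprocal influence of sequence-adjacent multi-omics
#'
#' Weights every pattern position by how strongly its sequence neighbours
#' are also its pathway neighbours.  For each adjacent couple
#' `(e_j, e_{j+1})` (plus the wrap-around `(e_n, e_1)` couple when
#' configured) all simple paths between the mapped nodes with edge length
#' `psi` in `1..apl_ceiling` are enumerated; the y-th path adds
#' `w = 1/psi_y` to the influence of every path node's pattern position
#' (path nodes absent from the pattern credit no position).  The summary
#' index RI is the median of the influence vector; RI = 0 means sequence
#' and pathway show no reciprocal influence and the MLS interactions carry
#' no real structural meaning.
#'
#' @param mls an [build_mls()] object (pattern length >= 2).
#' @param config a [mora_config()].
#' @return object of class `influence_vector`: list with `infl`
#'   (non-negative weights, one per pattern position) and `ri` (their
#'   median).
#' @export
mora <- function(mls, config) {
  stopifnot(inherits(mls, "mls"), inherits(config, "mora_config"))
  n <- length(mls$pattern$values)
  if (n < 2L) stop_mora("MORA needs a pattern of length >= 2")
  if (all(is.na(mls$mapping)))
    stop_mora("MORA needs at least one mapped pattern position")

  g <- mls$pathway$subgraph$graph
  if (config$undirected_search)
    g <- igraph::as_undirected(g, mode = "collapse")
  gnodes <- igraph::V(g)$name

  # node -> pattern positions it credits (merged operon nodes credit the
  # position of their run)
  node2pos <- list()
  for (j in seq_len(n)) {
    for (v in mls$merged[[j]])
      node2pos[[v]] <- c(node2pos[[v]], j)
  }

  couples <- cbind(seq_len(n - 1L), seq.int(2L, n))
  if (config$include_wraparound && n > 2L)
    couples <- rbind(couples, c(n, 1L))

  infl <- numeric(n)
  for (k in seq_len(nrow(couples))) {
    j1 <- couples[k, 1L]; j2 <- couples[k, 2L]
    a <- mls$mapping[j1]; b <- mls$mapping[j2]
    if (is.na(a) || is.na(b)) {
      warn_mora("couple (%d, %d): unmapped endpoint, skipped", j1, j2)
      next
    }
    if (!(a %in% gnodes) || !(b %in% gnodes) || a == b) next
    paths <- igraph::all_simple_paths(g, a, to = b,
                                      cutoff = config$apl_ceiling)
    for (p in paths) {
      psi <- length(p) - 1L
      if (psi < 1L) next
      w <- 1 / psi
      for (v in names(p)) {
        z <- node2pos[[v]]
        if (!is.null(z)) infl[z] <- infl[z] + w
      }
    }
  }
  structure(list(infl = infl, ri = stats::median(infl)),
            class = "influence_vector")
}

#' @export
print.influence_vector <- function(x, ...) {
  cat(sprintf("<influence_vector> RI=%.3f | %s\n", x$ri,
              paste(sprintf("%.2f", x$infl), collapse = " ")))
  invisible(x)
}

#' Adjacency class of a reciprocal influence
#'
#' Pathways with RI strictly above the threshold (default 1.5) are "more
#' adjacent": their gene order and reaction wiring reinforce each other.
#'
#' @param ri reciprocal influence (>= 0).
#' @param threshold decision threshold (default 1.5).
#' @return `"more_adjacent"` or `"less_adjacent"`.
#' @export
classify_adjacency <- function(ri, threshold = 1.5) {
  if (ri < 0) stop_mora("ri must be non-negative")
  if (ri > threshold) "more_adjacent" else "less_adjacent"
}

#' Export an influence vector as a data.frame
#'
#' @param x an `influence_vector`.
#' @param mls the MLS it was computed on.
#' @return data.frame with columns `position`, `gene_id`, `infl`.
#' @export
influence_table <- function(x, mls) {
  data.frame(position = seq_along(x$infl),
             gene_id = mls$pattern$positions,
             infl = x$infl,
             stringsAsFactors = FALSE)
}
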