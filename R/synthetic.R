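#' Structured synthetic networks
#'
#' Deterministic (seeded) generators for the reference topologies used to
#' validate the path-search and dyad machinery: `snake` (a chain of
#' reversible reactions), `clique`/`complete` (all pairs reversible),
#' `path_chain` (a one-way chain) and `gilbert` (each ordered node pair an
#' arc independently with probability `delta_p`).
#'
#' @param kind one of `"snake"`, `"clique"`, `"complete"`, `"path_chain"`,
#'   `"gilbert"`.
#' @param n number of nodes (>= 2).
#' @param delta_p arc probability, Gilbert kind only.
#' @param seed integer seed (Gilbert kind only; others are deterministic).
#' @param prefix node-id prefix.
#' @return a [metabolic_network].
#' @export
make_structured_graph <- function(kind = c("snake", "clique", "complete",
                                           "path_chain", "gilbert"),
                                  n, delta_p = 0.2, seed = 1L,
                                  prefix = "p") {
  kind <- match.arg(kind)
  if (!is_count(n) || n < 2L) stop_mora("n must be an integer >= 2")
  ids <- paste0(prefix, seq_len(n))
  edges <- switch(kind,
    snake = data.frame(from = ids[-n], to = ids[-1L], reversible = 1L),
    path_chain = data.frame(from = ids[-n], to = ids[-1L], reversible = 0L),
    clique = ,
    complete = {
      pr <- t(utils::combn(ids, 2L))
      data.frame(from = pr[, 1L], to = pr[, 2L], reversible = 1L)
    },
    gilbert = {
      if (delta_p < 0 || delta_p > 1) stop_mora("delta_p must be in [0,1]")
      all_pairs <- expand.grid(from = ids, to = ids,
                               stringsAsFactors = FALSE)
      all_pairs <- all_pairs[all_pairs$from != all_pairs$to, , drop = FALSE]
      keep <- with_seed_local(seed,
                              stats::runif(nrow(all_pairs)) < delta_p)
      d <- all_pairs[keep, , drop = FALSE]
      d$reversible <- 0L
      d
    })
  metabolic_network(edges, nodes = ids)
}

#' Synthetic organism with planted oscillation and dyadic structure
#'
#' Generates the four standard inputs (omics table, global network, gene
#' ordered pathways, operon map) with controlled statistical structure so
#' that every pipeline stage is testable without external data.  Genes get
#' genomic ranks `1..n_genes`; each pathway occupies a disjoint contiguous
#' rank block (bacterial pathway genes cluster on the chromosome).  A
#' target binary label is planted per gene: within each pathway,
#' consecutive-in-order genes alternate with probability
#' `oscillation_prob`; background genes are labeled at random.  Protein
#' abundance (log-normal), CAI (Beta) and per-treatment protein variation
#' (Gaussian) are drawn from label-separated families, then a bounded
#' repair loop nudges stragglers so that the organism-wide *and* the
#' pathway-local binary discretization both reproduce the planted labels
#' (planting operates on the post-discretization layer by construction).
#' Pathway subgraphs are Gilbert draws whose pair probability is tilted by
#' `anti_dyadic_bias`: opposite-label pairs connect with probability
#' `edge_prob * (1 + bias)`, equal-label pairs with
#' `edge_prob * (1 - bias)`; at bias 0 edges are independent of labels.
#'
#' @param n_genes genome size (default 1644, the scale of the integrated
#'   E. coli protein-centric network).
#' @param n_pathways number of pathways (default 66).
#' @param pathway_size genes per pathway (default 20).
#' @param operon_rate probability that a pathway gene extends the previous
#'   gene's operon (default 0.3).
#' @param n_treatments number of perturbation columns (default 69).
#' @param anti_dyadic_bias in \[0, 1): label-tilt of pathway edges.
#' @param oscillation_prob in \[0, 1\]: adjacent-gene alternation
#'   probability.
#' @param edge_prob baseline within-pathway pair probability (default 0.2).
#' @param background_prob arc probability between non-pathway pairs
#'   (default 0.01, keeps the global network connected without swamping
#'   pathway structure).
#' @param seed integer seed; all draws are pure functions of it.
#' @return list with `omics` ([omics_table]), `network`
#'   ([metabolic_network]), `pathways` (list of [gene_ordered_pathway]),
#'   `operons` ([operon_map]) and `truth` (planted labels and parameters).
#' @export
make_synthetic_organism <- function(n_genes = 1644L, n_pathways = 66L,
                                    pathway_size = 20L, operon_rate = 0.3,
                                    n_treatments = 69L,
                                    anti_dyadic_bias = 0.4,
                                    oscillation_prob = 0.6,
                                    edge_prob = 0.2,
                                    background_prob = 0.01,
                                    seed = 1L) {
  if (n_pathways * pathway_size > n_genes)
    stop_mora("n_pathways * pathway_size exceeds n_genes")
  if (anti_dyadic_bias < 0 || anti_dyadic_bias >= 1)
    stop_mora("anti_dyadic_bias must be in [0, 1)")
  with_seed_local(seed, {
    genes <- sprintf("b%04d", seq_len(n_genes))
    ranks <- stats::setNames(seq_len(n_genes), genes)

    # disjoint contiguous rank blocks, separated by random spare-gene gaps
    spare <- n_genes - n_pathways * pathway_size
    gap_alloc <- if (spare > 0L) {
      tabulate(sample.int(n_pathways + 1L, spare, replace = TRUE),
               nbins = n_pathways + 1L)
    } else rep(0L, n_pathways + 1L)
    starts <- integer(n_pathways)
    pos <- 1L
    for (i in seq_len(n_pathways)) {
      pos <- pos + gap_alloc[i]
      starts[i] <- pos
      pos <- pos + pathway_size
    }
    pw_members <- lapply(starts, function(s) genes[s:(s + pathway_size - 1L)])
    pw_ids <- sprintf("path:syn%05d", 10L * seq_len(n_pathways))

    # planted labels: alternate within pathways with prob oscillation_prob
    labels <- stats::setNames(sample(0:1, n_genes, replace = TRUE), genes)
    for (mem in pw_members) {
      lab <- integer(length(mem))
      lab[1L] <- sample(0:1, 1L)
      for (j in seq_along(mem)[-1L]) {
        flip <- stats::runif(1) < oscillation_prob
        lab[j] <- if (flip) 1L - lab[j - 1L] else lab[j - 1L]
      }
      labels[mem] <- lab
    }

    # label-separated omic families
    pa <- stats::rlnorm(n_genes, meanlog = ifelse(labels == 1L, 5.5, 2.0),
                        sdlog = 0.4)
    cai <- ifelse(labels == 1L,
                  stats::rbeta(n_genes, 9, 3),
                  stats::rbeta(n_genes, 3, 9))
    pv <- vapply(seq_len(n_treatments), function(t)
      stats::rnorm(n_genes, mean = 2.4 * (labels - 0.5), sd = 0.6),
      numeric(n_genes))

    # repair loop: force global and pathway-local steady discretization to
    # match the planted labels
    in_pw <- stats::setNames(rep(NA_integer_, n_genes), genes)
    for (i in seq_along(pw_members)) in_pw[pw_members[[i]]] <- i
    steady_sign <- function(pa, cai, scope) {
      z <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
      (z(pa[scope]) + z(cai[scope])) / 2
    }
    for (iter in seq_len(60L)) {
      bad <- character(0)
      s_g <- steady_sign(pa, cai, seq_len(n_genes))
      bad <- genes[(s_g >= 0) != (labels == 1L)]
      for (i in seq_along(pw_members)) {
        sc <- match(pw_members[[i]], genes)
        s_l <- steady_sign(pa, cai, sc)
        bad <- union(bad, pw_members[[i]][(s_l >= 0) != (labels[sc] == 1L)])
      }
      if (!length(bad)) break
      bi <- match(bad, genes)
      up <- labels[bi] == 1L
      pa[bi] <- ifelse(up, pa[bi] * 1.8, pa[bi] / 1.8)
      cai[bi] <- ifelse(up, 1 - (1 - cai[bi]) / 1.6, cai[bi] / 1.6)
    }
    if (length(bad))
      warn_mora("label planting unresolved for %d gene(s) after repair",
                length(bad))

    # network: biased Gilbert inside pathways, sparse background outside
    edge_from <- character(0); edge_to <- character(0)
    for (i in seq_along(pw_members)) {
      mem <- pw_members[[i]]
      pr <- utils::combn(mem, 2L)
      opp <- labels[pr[1L, ]] != labels[pr[2L, ]]
      p <- ifelse(opp, edge_prob * (1 + anti_dyadic_bias),
                  edge_prob * (1 - anti_dyadic_bias))
      keep <- stats::runif(ncol(pr)) < p
      edge_from <- c(edge_from, pr[1L, keep])
      edge_to <- c(edge_to, pr[2L, keep])
    }
    n_bg <- max(1L, round(background_prob * n_genes))
    bg_from <- sample(genes, n_bg * 4L, replace = TRUE)
    bg_to <- sample(genes, n_bg * 4L, replace = TRUE)
    bg_ok <- bg_from != bg_to
    edges <- data.frame(
      from = c(edge_from, bg_from[bg_ok]),
      to = c(edge_to, bg_to[bg_ok]),
      reversible = 1L, stringsAsFactors = FALSE)
    network <- metabolic_network(edges, nodes = genes)

    # operons: runs of consecutive pathway genes
    op_list <- list()
    op_i <- 0L
    for (i in seq_along(pw_members)) {
      mem <- pw_members[[i]]
      cur <- mem[1L]
      for (j in seq_along(mem)[-1L]) {
        if (stats::runif(1) < operon_rate) cur <- c(cur, mem[j])
        else {
          if (length(cur) > 1L) {
            op_i <- op_i + 1L
            op_list[[sprintf("op%04d", op_i)]] <- cur
          }
          cur <- mem[j]
        }
      }
      if (length(cur) > 1L) {
        op_i <- op_i + 1L
        op_list[[sprintf("op%04d", op_i)]] <- cur
      }
    }

    pv_df <- as.data.frame(pv)
    names(pv_df) <- sprintf("pv:t%02d", seq_len(n_treatments))
    omics <- omics_table(genes, pa, cai, pv_df)
    pathways <- stats::setNames(lapply(seq_along(pw_members), function(i)
      gene_ordered_pathway(pw_ids[i], pw_members[[i]], ranks[pw_members[[i]]],
                           network)), pw_ids)
    operons <- operon_map(op_list)
    list(omics = omics, network = network, pathways = pathways,
         operons = operons,
         truth = list(labels = labels,
                      params = list(n_genes = n_genes,
                                    n_pathways = n_pathways,
                                    pathway_size = pathway_size,
                                    operon_rate = operon_rate,
                                    n_treatments = n_treatments,
                                    anti_dyadic_bias = anti_dyadic_bias,
                                    oscillation_prob = oscillation_prob,
                                    edge_prob = edge_prob,
                                    background_prob = background_prob,
                                    seed = seed)))
  })
}

#' Minimal two-route MLS for tracing the MORA search
#'
#' A three-element pattern mapped on a triangle of reversible reactions:
#' every adjacent couple has both a direct reaction (edge length 1, weight
#' 1) and a two-step detour through the third node (weight 1/2).  With an
#' APL ceiling of 2 each couple credits its endpoints 1 + 1/2 and the
#' intermediate node 1/2; with a ceiling of 1 the detours contribute
#' nothing.
#'
#' @return an `mls` of length 3 with pattern `1-0-1`.
#' @export
make_two_route_mls <- function() {
  ids <- paste0("p", 1:3)
  net <- metabolic_network(data.frame(from = ids[c(1L, 2L, 3L)],
                                      to = ids[c(2L, 3L, 1L)],
                                      reversible = 1L))
  pw <- gene_ordered_pathway("path:demo", ids,
                             stats::setNames(1:3, ids), net)
  build_mls(pw, binary_pattern(c(1L, 0L, 1L), ids), setup = "plain")
}

#' Write the four standard input TSVs of a synthetic organism
#'
#' @param org result of [make_synthetic_organism()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths (plus a manifest
#'   of planted parameters).
#' @export
write_synthetic_inputs <- function(org, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(omics = file.path(dir, "omics.tsv"),
             network = file.path(dir, "network.tsv"),
             pathways = file.path(dir, "pathways.tsv"),
             operons = file.path(dir, "operons.tsv"),
             manifest = file.path(dir, "manifest.tsv"))
  write_omics_table(org$omics, paths[["omics"]])
  write_network(org$network, paths[["network"]])
  pw <- do.call(rbind, lapply(org$pathways, function(p)
    data.frame(pathway_id = p$pathway_id, gene_id = p$members,
               rank = unname(p$ranks), stringsAsFactors = FALSE)))
  utils::write.table(pw, paths[["pathways"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  op <- data.frame(
    operon_id = rep(names(org$operons), lengths(org$operons)),
    gene_id = unlist(org$operons, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(op, paths[["operons"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pars <- org$truth$params
  utils::write.table(
    data.frame(parameter = names(pars), value = unlist(pars)),
    paths[["manifest"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
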