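#' Observed dyad counts on a labeled pathway graph
#'
#' Classifies every directed arc of the subgraph by the binary labels of its
#' endpoints: arcs between opposite labels (`m10`, `m01`) carry the
#' anti-dyadic (oscillating) property, arcs between equal labels (`m11`,
#' `m00`) the dyadic one.  A reversible reaction, stored as two arcs,
#' contributes to both directions.  Also records the node counts per level
#' and the directed density `delta_p = M / (N (N - 1))`.
#'
#' @param graph a [metabolic_network] (typically a pathway subgraph) or a
#'   directed igraph.
#' @param labels named integer vector (0/1) covering every node.
#' @return object of class `dyad_stats` with observed fields filled
#'   (`n0`, `n1`, `N`, `M`, `delta_p`, `m10`, `m01`, `m11`, `m00`);
#'   expectation and magnitude fields are `NA` until [dyad_magnitudes()].
#' @export
count_dyads <- function(graph, labels) {
  g <- if (inherits(graph, "metabolic_network")) graph$graph else graph
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(labels)))
    stop_mora("unlabeled node(s): %s",
              paste(setdiff(nodes, names(labels)), collapse = ", "))
  lab <- labels[nodes]
  if (any(!lab %in% c(0L, 1L))) stop_mora("labels must be 0/1")
  N <- length(nodes)
  if (N < 2L) stop_mora("dyad counting needs at least 2 nodes")
  el <- igraph::as_edgelist(g, names = TRUE)
  lf <- lab[el[, 1L]]
  lt <- lab[el[, 2L]]
  M <- nrow(el)
  st <- list(n0 = sum(lab == 0L), n1 = sum(lab == 1L), N = N, M = M,
             delta_p = M / (N * (N - 1)),
             m10 = sum(lf == 1L & lt == 0L),
             m01 = sum(lf == 0L & lt == 1L),
             m11 = sum(lf == 1L & lt == 1L),
             m00 = sum(lf == 0L & lt == 0L),
             e10 = NA_real_, e01 = NA_real_, e11 = NA_real_, e00 = NA_real_,
             hat10 = NA_real_, hat01 = NA_real_, hat_anti = NA_real_,
             hat11 = NA_real_, hat00 = NA_real_, hat0011 = NA_real_)
  structure(st, class = "dyad_stats")
}

#' @export
print.dyad_stats <- function(x, ...) {
  cat(sprintf(
    "<dyad_stats> N=%d (n1=%d, n0=%d) M=%d dp=%.3f | m10=%d m01=%d m11=%d m00=%d\n",
    x$N, x$n1, x$n0, x$M, x$delta_p, x$m10, x$m01, x$m11, x$m00))
  if (!is.na(x$hat_anti))
    cat(sprintf("  hat10=%.3f hat01=%.3f hat_anti=%.3f hat11=%.3f hat00=%.3f hat0011=%.3f\n",
                x$hat10, x$hat01, x$hat_anti, x$hat11, x$hat00, x$hat0011))
  invisible(x)
}

#' Expected dyad counts under the density-based random model
#'
#' Gilbert-style expectations built from the directed density:
#' `e10 = e01 = n1 * n0 * delta_p`, `e00 = choose(n0, 2) * delta_p`,
#' `e11 = choose(n1, 2) * delta_p`.  Note the anti-dyadic expectations count
#' ordered pairs while the dyadic ones count unordered pairs; the model is
#' used exactly as defined (see the package vignette for the consequences).
#'
#' @param n0,n1 node counts per level.
#' @param delta_p directed density in \[0, 1\].
#' @return named list `e10`, `e01`, `e11`, `e00`.
#' @export
expected_dyads <- function(n0, n1, delta_p) {
  list(e10 = n1 * n0 * delta_p,
       e01 = n1 * n0 * delta_p,
       e11 = n1 * (n1 - 1) / 2 * delta_p,
       e00 = n0 * (n0 - 1) / 2 * delta_p)
}

#' Dyadic-effect magnitudes (observed / expected)
#'
#' Fills the expectation and magnitude fields of a [count_dyads()] result:
#' `hat10 = m10 / e10` (the anti-dyadic magnitude), `hat11`, `hat00`
#' likewise, `hat_anti = (m10 + m01) / (e10 + e01)` (the symmetric
#' anti-dyadic magnitude reported by the pipeline, equal to `hat10` whenever
#' `m10 = m01` as in fully reversible networks), and the average dyadic
#' effect `hat0011 = (hat11 + hat00) / 2`.  Any magnitude with zero
#' expectation is left missing rather than infinite.
#'
#' @param stats a `dyad_stats` from [count_dyads()].
#' @return the `dyad_stats` with hats filled.
#' @export
dyad_magnitudes <- function(stats) {
  e <- expected_dyads(stats$n0, stats$n1, stats$delta_p)
  stats[c("e10", "e01", "e11", "e00")] <- e
  rat <- function(m, e) if (is.na(e) || e <= 0) NA_real_ else m / e
  stats$hat10 <- rat(stats$m10, e$e10)
  stats$hat01 <- rat(stats$m01, e$e01)
  stats$hat_anti <- rat(stats$m10 + stats$m01, e$e10 + e$e01)
  stats$hat11 <- rat(stats$m11, e$e11)
  stats$hat00 <- rat(stats$m00, e$e00)
  both <- c(stats$hat11, stats$hat00)
  stats$hat0011 <- if (all(is.na(both))) NA_real_ else mean(both, na.rm = TRUE)
  stats
}

#' Mainly-oscillating predicate
#'
#' A pathway network is mainly oscillating when its anti-dyadic magnitude
#' strictly exceeds both dyadic magnitudes: `hat10 > hat11` and
#' `hat10 > hat00`.  Undefined magnitudes (zero expectation, degenerate
#' label counts) are treated as 0 in the comparison, with a warning.
#'
#' @param stats a `dyad_stats` with magnitudes filled.
#' @return logical scalar.
#' @export
mainly_oscillating <- function(stats) {
  h <- c(hat10 = stats$hat10, hat11 = stats$hat11, hat00 = stats$hat00)
  if (anyNA(h)) {
    warn_mora("undefined magnitude(s) (%s) treated as 0 in mainly_oscillating",
              paste(names(h)[is.na(h)], collapse = ", "))
    h[is.na(h)] <- 0
  }
  h[["hat10"]] > h[["hat11"]] && h[["hat10"]] > h[["hat00"]]
}

# Count one observable for a given set of 1-labeled vertex indices.
#' @noRd
dyad_count_for <- function(ef, et, ones, observable) {
  f1 <- ef %in% ones
  t1 <- et %in% ones
  switch(observable,
         m10 = sum(f1 & !t1),
         m01 = sum(!f1 & t1),
         m11 = sum(f1 & t1),
         m00 = sum(!f1 & !t1),
         stop_mora("unknown observable '%s'", observable))
}

#' Exact placement-null distribution of a dyad count
#'
#' Enumerates all `choose(N, n1)` placements of the `n1` one-labels on the
#' node set and returns the exact distribution of the chosen dyad count
#' under uniform placement.  Refuses instances above the configuration cap
#' (default 1e6 placements), for which [montecarlo_null()] is the intended
#' tool.
#'
#' @param graph a [metabolic_network] or directed igraph.
#' @param n1 number of nodes labeled 1.
#' @param observable one of `"m10"`, `"m01"`, `"m11"`, `"m00"`.
#' @param observed optional observed count; if given, the upper tail
#'   probability `P(X >= observed)` is returned.
#' @param cap maximum number of configurations to enumerate.
#' @return list with `values`, `prob` (the support and probabilities),
#'   `mean`, and `p_upper` (or `NA` if `observed` is missing).
#' @export
enumerate_null <- function(graph, n1, observable = "m10", observed = NULL,
                           cap = 1e6) {
  g <- if (inherits(graph, "metabolic_network")) graph$graph else graph
  N <- igraph::vcount(g)
  if (n1 < 0L || n1 > N) stop_mora("n1 must be in 0..N")
  n_conf <- choose(N, n1)
  if (n_conf > cap)
    stop_mora(paste0("choose(%d, %d) = %.3g exceeds the enumeration cap ",
                     "(%.3g); use montecarlo_null"), N, n1, n_conf, cap)
  el <- igraph::as_edgelist(g, names = FALSE)
  ef <- el[, 1L]; et <- el[, 2L]
  counts <- if (n1 == 0L || n1 == N) {
    dyad_count_for(ef, et, if (n1 == N) seq_len(N) else integer(0), observable)
  } else {
    utils::combn(N, n1, function(ones)
      dyad_count_for(ef, et, ones, observable))
  }
  tab <- table(counts)
  values <- as.integer(names(tab))
  prob <- as.numeric(tab) / length(counts)
  list(values = values, prob = prob,
       mean = sum(values * prob),
       p_upper = if (is.null(observed)) NA_real_
                 else sum(prob[values >= observed]))
}

#' Monte-Carlo placement-null distribution of a dyad count
#'
#' Samples uniform placements of `n1` one-labels; the seeded sampler makes
#' runs reproducible and its mean converges to the [enumerate_null()] mean.
#'
#' @inheritParams enumerate_null
#' @param reps number of sampled placements (>= 1).
#' @param seed integer seed for the sampler.
#' @return list with `samples`, `mean`, `sd`, and `p_upper` as in
#'   [enumerate_null()].
#' @export
montecarlo_null <- function(graph, n1, observable = "m10", reps = 1000L,
                            seed = 1L, observed = NULL) {
  if (reps < 1L) stop_mora("reps must be >= 1")
  g <- if (inherits(graph, "metabolic_network")) graph$graph else graph
  N <- igraph::vcount(g)
  if (n1 < 0L || n1 > N) stop_mora("n1 must be in 0..N")
  el <- igraph::as_edgelist(g, names = FALSE)
  ef <- el[, 1L]; et <- el[, 2L]
  samples <- with_seed_local(seed, vapply(seq_len(reps), function(i)
    dyad_count_for(ef, et, sample.int(N, n1), observable), numeric(1)))
  list(samples = samples, mean = mean(samples), sd = stats::sd(samples),
       p_upper = if (is.null(observed)) NA_real_
                 else mean(samples >= observed))
}
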