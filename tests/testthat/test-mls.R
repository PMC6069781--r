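test_that("MLS assembly validates membership and gene order", {
  net <- make_structured_graph("snake", 4, prefix = "g")
  ids <- paste0("g", 1:4)
  pw <- gene_ordered_pathway("path:x", ids, stats::setNames(1:4, ids), net)
  m <- build_mls(pw, binary_pattern(c(1, 0, 1, 0), ids))
  expect_s3_class(m, "mls")
  expect_equal(m$mapping, ids)
  expect_error(build_mls(pw, binary_pattern(c(1, 0), c("g1", "zz"))),
               "not in pathway")
  expect_error(build_mls(pw, binary_pattern(c(1, 0), c("g2", "g1"))),
               "gene order")
})

test_that("swapping two genes in the order permutes the pattern values", {
  net <- make_structured_graph("complete", 4, prefix = "g")
  ids <- paste0("g", 1:4)
  vals <- c(1L, 1L, 0L, 1L)
  pw <- gene_ordered_pathway("path:x", ids, stats::setNames(1:4, ids), net)
  # swap the ranks of g2 and g3: the sequence (and pattern) swaps with them
  pw_sw <- gene_ordered_pathway("path:x", ids,
                                stats::setNames(c(1L, 3L, 2L, 4L), ids), net)
  names(vals) <- ids
  m <- build_mls(pw, binary_pattern(vals[pw$members], pw$members))
  m_sw <- build_mls(pw_sw, binary_pattern(vals[pw_sw$members], pw_sw$members))
  expect_equal(m_sw$pattern$positions, c("g1", "g3", "g2", "g4"))
  expect_equal(m_sw$pattern$values, unname(vals[c(1, 3, 2, 4)]))
})

opc_fixture <- function(vals, operon_members) {
  ids <- paste0("g", seq_along(vals))
  net <- make_structured_graph("snake", length(vals), prefix = "g")
  pw <- gene_ordered_pathway("path:x", ids,
                             stats::setNames(seq_along(ids), ids), net)
  m <- build_mls(pw, binary_pattern(vals, ids))
  list(mls = m, operons = operon_map(list(op1 = operon_members)))
}

test_that("operon compression takes the modal value of each contiguous run", {
  fx <- opc_fixture(c(1, 1, 0, 0, 1), c("g2", "g3", "g4"))
  out <- operon_compression(fx$mls, fx$operons)
  expect_equal(out$pattern$values, c(1L, 0L, 1L))          # run 1,0,0 -> 0
  expect_equal(out$pattern$positions, c("g1", "g2", "g5"))
  expect_setequal(out$merged[[2]], c("g2", "g3", "g4"))
  expect_equal(out$mapping[2], "g2")                       # first member

  fx2 <- opc_fixture(c(0, 1, 1, 0, 0), c("g2", "g3", "g4"))
  expect_equal(operon_compression(fx2$mls, fx2$operons)$pattern$values,
               c(0L, 1L, 0L))                              # run 1,1,0 -> 1
})

test_that("even-run value ties fall to the first element, with a warning", {
  fx <- opc_fixture(c(1, 1, 0, 1), c("g2", "g3"))
  expect_warning(out <- operon_compression(fx$mls, fx$operons), "tie")
  expect_equal(out$pattern$values, c(1L, 1L, 1L))
  fx2 <- opc_fixture(c(1, 0, 1, 1), c("g2", "g3"))
  expect_warning(out2 <- operon_compression(fx2$mls, fx2$operons), "tie")
  expect_equal(out2$pattern$values[2], 0L)
})

test_that("compression preserves order, shortens by run excess, and is idempotent", {
  fx <- opc_fixture(c(1, 0, 0, 1, 0, 1), c("g2", "g3", "g4"))
  out <- operon_compression(fx$mls, fx$operons)
  expect_equal(length(out$pattern$values),
               6L - (3L - 1L))
  again <- operon_compression(out, fx$operons)
  expect_equal(again$pattern$values, out$pattern$values)
  expect_equal(again$mapping, out$mapping)
})

test_that("non-contiguous operon members in the pattern are an error", {
  fx <- opc_fixture(c(1, 0, 1, 0), c("g1", "g3"))
  expect_error(operon_compression(fx$mls, fx$operons), "non-contiguous")
})

# --- path extension -------------------------------------------------------

# global net: pathway chain p1-p2-p3-p4 plus two detours around the
# non-oscillating (p3, p4) pair: via p5 (value alternates with both
# endpoints) and via p8 (value equal to the endpoints)
ext_fixture <- function(vals = c(1, 0, 1, 1)) {
  ids <- paste0("p", 1:8)
  edges <- data.frame(
    from = c("p1", "p2", "p3", "p3", "p5", "p3", "p8"),
    to = c("p2", "p3", "p4", "p5", "p4", "p8", "p4"),
    reversible = 1)
  net <- metabolic_network(edges, nodes = ids)
  pw <- gene_ordered_pathway("path:x", paste0("p", 1:4),
                             stats::setNames(1:4, paste0("p", 1:4)), net)
  m <- build_mls(pw, binary_pattern(vals, paste0("p", 1:4)))
  gvals <- c(p1 = 1L, p2 = 0L, p3 = 1L, p4 = 1L, p5 = 0L, p8 = 1L)
  list(mls = m, net = net, gvals = gvals)
}

test_that("path extension picks the most oscillating shortest detour", {
  fx <- ext_fixture()
  out <- path_extension(fx$mls, fx$net, fx$gvals, mora_config(2))
  expect_equal(out$pattern$positions, c("p1", "p2", "p3", "p5", "p4"))
  expect_equal(out$pattern$values, c(1L, 0L, 1L, 0L, 1L))
  expect_true("p5" %in% network_nodes(out$pathway$subgraph))
  # inserted nodes removable: dropping them recovers the original pattern
  keep <- !out$inserted
  expect_equal(out$pattern$values[keep], fx$mls$pattern$values)
  expect_equal(out$pattern$positions[keep], fx$mls$pattern$positions)
})

test_that("a fully oscillating pattern is returned unchanged", {
  fx <- ext_fixture(vals = c(1, 0, 1, 0))
  out <- path_extension(fx$mls, fx$net, fx$gvals, mora_config(2))
  expect_identical(out$pattern$values, fx$mls$pattern$values)
  expect_identical(out$pattern$positions, fx$mls$pattern$positions)
})

test_that("equal-score equal-length detours resolve lexicographically with a warning", {
  fx <- ext_fixture()
  gv <- fx$gvals
  gv["p8"] <- 0L  # now both detours alternate equally
  expect_warning(out <- path_extension(fx$mls, fx$net, gv, mora_config(2)),
                 "tie")
  expect_equal(out$pattern$positions[4], "p5")  # p3-p5-p4 < p3-p8-p4
})

test_that("candidates through unvalued nodes are discarded with a warning", {
  fx <- ext_fixture()
  gv <- fx$gvals[setdiff(names(fx$gvals), "p5")]
  expect_warning(out <- path_extension(fx$mls, fx$net, gv, mora_config(2)),
                 "unvalued")
  # the p8 detour (same values as endpoints) is then the best remaining
  expect_equal(out$pattern$positions[4], "p8")
})

test_that("extension never removes elements and is idempotent once oscillating", {
  fx <- ext_fixture()
  out <- path_extension(fx$mls, fx$net, fx$gvals, mora_config(2))
  expect_gte(length(out$pattern$values), length(fx$mls$pattern$values))
  again <- path_extension(out, fx$net, fx$gvals, mora_config(2))
  expect_identical(again$pattern$values, out$pattern$values)
})

test_that("pattern labels propagate to every merged node for dyad counting", {
  fx <- opc_fixture(c(1, 0, 0, 0, 1), c("g2", "g3", "g4"))
  out <- operon_compression(fx$mls, fx$operons)
  lab <- mls_node_labels(out)
  expect_equal(unname(lab[c("g2", "g3", "g4")]), rep(0L, 3))
  expect_equal(unname(lab[c("g1", "g5")]), c(1L, 1L))
})
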