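test_that("structured graphs have the expected arc counts", {
  expect_equal(nrow(net_arcs(make_structured_graph("clique", 4))), 12L)
  expect_equal(nrow(net_arcs(make_structured_graph("snake", 5))), 8L)
  expect_equal(nrow(net_arcs(make_structured_graph("path_chain", 5))), 4L)
  expect_error(make_structured_graph("snake", 1), "n must be")
})

test_that("gilbert graphs hit the binomial arc-count band and are seeded", {
  # 50 nodes, 2450 ordered pairs, p = 0.1: binomial 99% interval
  n_arcs <- nrow(net_arcs(make_structured_graph("gilbert", 50, 0.1,
                                                seed = 123)))
  band <- qbinom(c(0.005, 0.995), 2450, 0.1)
  expect_gte(n_arcs, band[1])
  expect_lte(n_arcs, band[2])
  a <- net_arcs(make_structured_graph("gilbert", 20, 0.2, seed = 7))
  b <- net_arcs(make_structured_graph("gilbert", 20, 0.2, seed = 7))
  expect_identical(a, b)
  expect_error(make_structured_graph("gilbert", 10, delta_p = 1.2), "delta_p")
})

test_that("the synthetic organism is a pure function of its seed", {
  args <- list(n_genes = 80, n_pathways = 2, pathway_size = 8,
               n_treatments = 2, seed = 31)
  o1 <- do.call(make_synthetic_organism, args)
  o2 <- do.call(make_synthetic_organism, args)
  expect_identical(o1$omics, o2$omics)
  expect_identical(net_arcs(o1$network), net_arcs(o2$network))
  expect_identical(o1$truth$labels, o2$truth$labels)
  d1 <- tempfile(); d2 <- tempfile()
  write_synthetic_inputs(o1, d1)
  write_synthetic_inputs(o2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("planted labels survive both the global and the local discretization", {
  org <- make_synthetic_organism(n_genes = 150, n_pathways = 4,
                                 pathway_size = 10, n_treatments = 2,
                                 oscillation_prob = 0.5, seed = 17)
  gv <- global_binary_values(org$omics, "steady")
  expect_identical(unname(gv[names(org$truth$labels)]),
                   unname(org$truth$labels))
  for (pw in org$pathways) {
    ev <- suppressMessages(effect_vectors(org$omics, pw, "steady"))
    b <- binarize(ev)
    expect_identical(b$mov1$values,
                     unname(org$truth$labels[ev$gene_ids]))
  }
})

test_that("fully planted oscillation yields sigma_obs exactly 1 on every pathway", {
  org <- make_synthetic_organism(n_genes = 150, n_pathways = 5,
                                 pathway_size = 10, n_treatments = 2,
                                 oscillation_prob = 1, seed = 23)
  for (pw in org$pathways) {
    ev <- suppressMessages(effect_vectors(org$omics, pw, "steady"))
    b <- binarize(ev)
    comb <- combine_local_global(b$mov1, b$mov2)
    expect_equal(similarity(comb)$sigma_obs, 1)
  }
})

test_that("unbiased pathway wiring calibrates the anti-dyadic magnitude at 1", {
  # bias 0: edges independent of labels, so over many replicate pathways the
  # mean anti-dyadic magnitude sits within 3 SE of 1
  hats <- numeric(0)
  for (seed in 1:10) {
    org <- make_synthetic_organism(n_genes = 400, n_pathways = 20,
                                   pathway_size = 12, n_treatments = 1,
                                   anti_dyadic_bias = 0, edge_prob = 0.35,
                                   oscillation_prob = 0.5,
                                   seed = 600 + seed)
    for (pw in org$pathways) {
      lab <- org$truth$labels[pw$members]
      if (sum(lab == 1) < 2 || sum(lab == 0) < 2) next
      d <- dyad_magnitudes(count_dyads(pw$subgraph, lab))
      if (!is.na(d$hat_anti)) hats <- c(hats, d$hat_anti)
    }
  }
  expect_gt(length(hats), 150)
  se <- sd(hats) / sqrt(length(hats))
  expect_lt(abs(mean(hats) - 1), 3 * se)
})

test_that("recovered scores increase monotonically in the planted parameters", {
  grid <- c(0.1, 0.5, 0.9)
  mean_sigma <- vapply(seq_along(grid), function(i) {
    # at extreme oscillation probabilities some pathways are label-monochrome
    # and the local-planting repair cannot fully resolve; that is expected
    org <- suppressWarnings(
      make_synthetic_organism(n_genes = 400, n_pathways = 25,
                              pathway_size = 10, n_treatments = 1,
                              oscillation_prob = grid[i],
                              seed = 700 + i))
    mean(vapply(org$pathways, function(pw) {
      ev <- suppressMessages(effect_vectors(org$omics, pw, "steady"))
      b <- binarize(ev)
      similarity(combine_local_global(b$mov1, b$mov2))$sigma_obs
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_sigma) > 0))

  mean_anti <- vapply(seq_along(grid), function(i) {
    org <- make_synthetic_organism(n_genes = 400, n_pathways = 25,
                                   pathway_size = 12, edge_prob = 0.35,
                                   n_treatments = 1,
                                   anti_dyadic_bias = grid[i],
                                   seed = 800 + i)
    hats <- vapply(org$pathways, function(pw) {
      lab <- org$truth$labels[pw$members]
      if (sum(lab == 1) < 2 || sum(lab == 0) < 2) return(NA_real_)
      dyad_magnitudes(count_dyads(pw$subgraph, lab))$hat_anti
    }, numeric(1))
    mean(hats, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_anti) > 0))
})

test_that("the written synthetic inputs feed straight back into the readers", {
  org <- make_synthetic_organism(n_genes = 90, n_pathways = 2,
                                 pathway_size = 8, n_treatments = 2,
                                 seed = 41)
  dir <- tempfile()
  paths <- write_synthetic_inputs(org, dir)
  omics <- read_omics_table(paths[["omics"]])
  net <- read_network(paths[["network"]])
  pws <- read_pathways(paths[["pathways"]], net)
  ops <- read_operons(paths[["operons"]])
  expect_equal(nrow(omics), 90L)
  # the edge-list dialect keeps every non-isolated node
  expect_true(all(network_nodes(net) %in% network_nodes(org$network)))
  expect_length(pws, 2L)
  expect_s3_class(ops, "operon_map")
  rows <- suppressMessages(run_pipeline(omics, net, pws, ops,
                                        setups = "plain",
                                        conditions = "steady"))
  expect_equal(nrow(rows), 2L)
})
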