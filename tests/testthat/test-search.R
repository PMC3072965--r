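# Stochastic search: core algorithm, refinements, multilevel recursion.

test_that("core search finds the optimum of clearly separated modules", {
  net <- two_triangles()
  fl <- network_flow(net)
  for (s in 1:5) {
    mem <- core_partition(fl, seed = s)
    expect_equal(max(mem), 2L)
    expect_equal(two_level_codelength(fl, mem)$total_bits, log2(3),
                 tolerance = 1e-12)
  }
  # complete graph: a single module is optimal
  k5 <- network_flow(complete_graph(5))
  res <- multilevel_search(complete_graph(5), seed = 1, n_restarts = 5,
                           flow = k5)
  expect_equal(res$codelength, log2(5), tolerance = 1e-12)
  expect_equal(n_levels(res$partition), 2L)
})

test_that("core result never exceeds the singleton-partition codelength", {
  withr::local_seed(23)
  for (i in 1:5) {
    net <- random_connected_graph(sample(6:14, 1), 0.3)
    fl <- network_flow(net)
    mem <- core_partition(fl, seed = i)
    expect_lte(two_level_codelength(fl, mem)$total_bits,
               two_level_codelength(fl, seq_len(net$n_nodes))$total_bits + 1e-12)
  }
})

test_that("refinements fix planted defects and never increase codelength", {
  net <- two_triangles()
  fl <- network_flow(net)
  optimum <- c(1, 1, 1, 2, 2, 2)
  # optimal partition is a fixed point of both refinements
  expect_equal(refine_submodules(fl, optimum, seed = 1), optimum)
  expect_equal(refine_single_nodes(fl, optimum, seed = 1), optimum)
  # merged pair of triangles is split again by submodule movements
  merged <- rep(1, 6)
  ref <- refine_submodules(fl, merged, seed = 2)
  expect_equal(two_level_codelength(fl, ref)$total_bits, log2(3),
               tolerance = 1e-12)
  # a single mislabeled node is corrected by single-node movements
  wrong <- c(1, 1, 2, 2, 2, 2)
  ref2 <- refine_single_nodes(fl, wrong, seed = 3)
  expect_equal(two_level_codelength(fl, ref2)$total_bits, log2(3),
               tolerance = 1e-12)
  # monotonicity on random partitions of random graphs
  withr::local_seed(31)
  for (i in 1:5) {
    rnet <- random_connected_graph(10, 0.3)
    rfl <- network_flow(rnet)
    init <- sample.int(4, 10, replace = TRUE)
    L0 <- two_level_codelength(rfl, init)$total_bits
    expect_lte(two_level_codelength(rfl, refine_single_nodes(rfl, init))$total_bits,
               L0 + 1e-12)
    expect_lte(two_level_codelength(rfl, refine_submodules(rfl, init))$total_bits,
               L0 + 1e-12)
  }
})

test_that("multilevel search recovers the worked-example hierarchy from any seed", {
  fx <- triangle_hierarchy_network()
  fl <- network_flow(fx$network)
  for (s in c(1, 2, 99)) {
    res <- multilevel_search(fx$network, seed = s, n_restarts = 10, flow = fl)
    expect_equal(res$codelength, 3.4841898804052187, tolerance = 1e-9)
    expect_equal(n_levels(res$partition), 3L)
    sl <- level_slices(res$partition)
    expect_equal(max(sl$top), 3L)
    expect_equal(max(sl$finest), 9L)
    # finest level agrees with the planted triangles
    expect_equal(normalized_mutual_information(sl$finest, fx$triangles), 1)
  }
})

test_that("no superfluous levels are added where depth-2 is optimal", {
  for (net in list(two_triangles(), complete_graph(5))) {
    res <- multilevel_search(net, seed = 4, n_restarts = 5)
    expect_equal(n_levels(res$partition), 2L)
  }
})

test_that("search is deterministic given the seed and improves with restarts", {
  fx <- triangle_hierarchy_network()
  fl <- network_flow(fx$network)
  a <- multilevel_search(fx$network, seed = 8, n_restarts = 3, flow = fl)
  b <- multilevel_search(fx$network, seed = 8, n_restarts = 3, flow = fl)
  expect_identical(a$partition$paths, b$partition$paths)
  withr::local_seed(2)
  net <- random_connected_graph(16, 0.25)
  fl2 <- network_flow(net)
  prev <- Inf
  for (k in c(1, 3, 6)) {
    res <- multilevel_search(net, seed = 5, n_restarts = k, flow = fl2)
    expect_lte(res$codelength, prev + 1e-12)
    prev <- res$codelength
  }
})

test_that("reported codelength equals the evaluator re-run on the partition", {
  withr::local_seed(13)
  for (i in 1:4) {
    net <- random_connected_graph(sample(8:16, 1), 0.3)
    res <- multilevel_search(net, seed = i, n_restarts = 3)
    expect_equal(res$codelength,
                 hierarchical_codelength(res$flow, res$partition)$total_bits,
                 tolerance = 1e-9)
  }
})

test_that("two-level search matches exhaustive enumeration on small graphs", {
  withr::local_seed(41)
  graphs <- c(connected_graph_classes(4), connected_graph_classes(5))
  parts <- list(`4` = all_set_partitions(4), `5` = all_set_partitions(5))
  for (net in graphs) {
    fl <- network_flow(net)
    oracle <- brute_force_min_two_level(fl,
                                        parts[[as.character(net$n_nodes)]])
    found <- multilevel_search(net, seed = 7, n_restarts = 5,
                               two_level = TRUE, flow = fl)
    expect_equal(found$codelength, oracle$bits, tolerance = 1e-10)
  }
})

test_that("multilevel search matches exhaustive hierarchy enumeration on the 7-node path", {
  net <- path_graph(7)
  fl <- network_flow(net)
  oracle <- brute_force_min_hierarchy(fl)
  res <- multilevel_search(net, seed = 3, n_restarts = 10, flow = fl)
  expect_equal(res$codelength, oracle, tolerance = 1e-10)
})

test_that("the finest level agrees with igraph's independent flat optimizer", {
  fx <- triangle_hierarchy_network()
  g <- as_igraph(fx$network)
  set.seed(1)
  cm <- igraph::cluster_infomap(g, nb.trials = 10)
  expect_equal(normalized_mutual_information(igraph::membership(cm),
                                             fx$triangles), 1)
})

test_that("compression gain is the relative index saving, floored at zero", {
  fx <- triangle_hierarchy_network()
  fl <- network_flow(fx$network)
  gain <- compression_gain(fx$network, seed = 2, n_restarts = 5, flow = fl)
  expect_equal(gain, 100 * (3.5722858 - 3.4841899) / 3.5722858,
               tolerance = 1e-4)
  expect_equal(compression_gain(complete_graph(5), seed = 1, n_restarts = 3), 0)
})
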