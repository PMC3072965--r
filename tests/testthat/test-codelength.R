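# Two-level and hierarchical map equation values and properties.

# closed-form worked-example codelengths, derived by hand from the degree
# sequence (24 nodes of degree 3, 3 of degree 2, total degree 78) before any
# implementation run:
#  one module    : H(p) = -(24*(3/78)log2(3/78) + 3*(2/78)log2(2/78))
#  nine triangles: q H(Q) + module terms with exit counts {3x6, 2x3}/78
#  3x3x3 tree    : root (6/78)log2(3) + three subindex + nine module terms
ONE_MODULE_BITS <- 4.745436833581181
NINE_TRIANGLE_BITS <- 3.5722858056149613
HIERARCHY_BITS <- 3.4841898804052187

test_that("worked-example codelengths match the closed-form derivation", {
  fx <- triangle_hierarchy_network()
  fl <- network_flow(fx$network)
  expect_equal(two_level_codelength(fl, rep(1, 27))$total_bits,
               ONE_MODULE_BITS, tolerance = 1e-12)
  expect_equal(two_level_codelength(fl, fx$triangles)$total_bits,
               NINE_TRIANGLE_BITS, tolerance = 1e-12)
  expect_equal(hierarchical_codelength(fl, fx$partition)$total_bits,
               HIERARCHY_BITS, tolerance = 1e-12)
})

test_that("disconnected triangles give pure within-module entropies", {
  fl <- network_flow(two_triangles())
  # two modules: zero exit rates, each codebook is uniform over three nodes
  expect_equal(two_level_codelength(fl, c(1, 1, 1, 2, 2, 2))$total_bits,
               log2(3), tolerance = 1e-12)
  expect_equal(two_level_codelength(fl, rep(1, 6))$total_bits,
               log2(6), tolerance = 1e-12)
})

test_that("one-module codelength equals the entropy of the visit rates", {
  withr::local_seed(3)
  for (i in 1:5) {
    net <- random_connected_graph(sample(5:12, 1), 0.4)
    fl <- network_flow(net)
    expect_equal(two_level_codelength(fl, rep(1, net$n_nodes))$total_bits,
                 -sum(ifelse(fl$node_rate > 0,
                             fl$node_rate * log2(fl$node_rate), 0)),
                 tolerance = 1e-12)
  }
})

test_that("hierarchical reduces to two-level on depth-2 trees", {
  withr::local_seed(17)
  for (i in 1:25) {
    net <- random_connected_graph(sample(4:12, 1), 0.35)
    fl <- network_flow(net)
    mem <- sample.int(3, net$n_nodes, replace = TRUE)
    expect_equal(hierarchical_codelength(fl, as_hpartition(mem))$total_bits,
                 two_level_codelength(fl, mem)$total_bits,
                 tolerance = 1e-12)
  }
})

test_that("codelength is invariant under node and sibling relabelling", {
  fx <- triangle_hierarchy_network()
  fl <- network_flow(fx$network)
  withr::local_seed(5)
  perm <- sample.int(27)
  l <- fx$network$links
  pnet <- flow_network(data.frame(from = perm[l$from], to = perm[l$to],
                                  weight = l$weight), n_nodes = 27)
  pfl <- network_flow(pnet)
  ppart <- hpartition(fx$partition$paths[order(perm)])
  expect_equal(hierarchical_codelength(pfl, ppart)$total_bits,
               HIERARCHY_BITS, tolerance = 1e-12)
  # reorder sibling modules
  shuf <- lapply(fx$partition$paths, function(p) c(4 - p[1], p[2]))
  expect_equal(hierarchical_codelength(fl, hpartition(shuf))$total_bits,
               HIERARCHY_BITS, tolerance = 1e-12)
})

test_that("index terms decompose: hierarchy saves on the index codebooks only", {
  fx <- triangle_hierarchy_network()
  fl <- network_flow(fx$network)
  two <- two_level_codelength(fl, fx$triangles)
  hier <- hierarchical_codelength(fl, fx$partition)
  expect_equal(two$module_bits, hier$module_bits, tolerance = 1e-12)
  expect_equal(two$index_bits - hier$index_bits,
               two$total_bits - hier$total_bits, tolerance = 1e-12)
  expect_equal(hier$total_bits,
               hier$root_bits + sum(hier$vertices$bits), tolerance = 1e-12)
})

test_that("partition containers validate and canonicalize", {
  fl <- network_flow(two_triangles())
  expect_error(two_level_codelength(fl, c(1, 1, 2)), "6")
  expect_error(hpartition(list()), "non-empty")
  expect_error(hpartition(list(integer(0))), "positive")
  # single-internal-child chains collapse; one-module partitions survive
  hp <- hpartition(list(c(1, 1), c(1, 1), c(1, 2), c(1, 2), c(1, 3), c(1, 3)))
  expect_equal(n_levels(hp), 2L)
  one <- hpartition(list(1, 1, 1))
  expect_equal(n_levels(one), 2L)
  expect_equal(lengths(one$paths), rep(1L, 3))
})

test_that("mixed-depth trees evaluate every branch at its own depth", {
  fl <- network_flow(two_triangles())
  # one triangle split one level deeper than the other
  hp <- hpartition(list(c(1, 1), c(1, 1), c(1, 2), 2, 2, 2),
                   canonical = FALSE)
  r <- hierarchical_codelength(fl, hp)
  expect_equal(n_levels(hp), 3L)
  expect_true(is.finite(r$total_bits))
  expect_gte(r$total_bits, 0)
  sl <- level_slices(hp)
  expect_equal(max(sl$top), 2L)
  expect_equal(max(sl$finest), 3L)
})
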