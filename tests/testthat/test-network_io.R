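# Edge-list and Pajek readers/writers.

test_that("edge lists parse, remap labels and aggregate duplicates", {
  f <- withr::local_tempfile(lines = c("a b", "b c", "c a"))
  net <- read_edge_list(f)
  expect_equal(net$n_nodes, 3L)
  expect_equal(nrow(net$links), 3L)
  expect_equal(sum(node_strength(net)), 6)
  expect_equal(net$node_names, c("a", "b", "c"))

  f2 <- withr::local_tempfile(lines = c("0 1 2.0", "0 1 3.0"))
  net2 <- read_edge_list(f2)
  expect_equal(nrow(net2$links), 1L)
  expect_equal(net2$links$weight, 5.0)

  # undirected: reversed duplicates aggregate too
  f3 <- withr::local_tempfile(lines = c("u v 1", "v u 2"))
  expect_equal(read_edge_list(f3)$links$weight, 3)
  expect_equal(nrow(read_edge_list(f3, directed = TRUE)$links), 2L)
})

test_that("malformed, non-positive-weight and empty edge lists are rejected", {
  bad <- withr::local_tempfile(lines = c("a b", "a b c d"))
  expect_error(read_edge_list(bad), "line 2")
  neg <- withr::local_tempfile(lines = c("a b -1"))
  expect_error(read_edge_list(neg), "weight")
  zero <- withr::local_tempfile(lines = c("a b 0"))
  expect_error(read_edge_list(zero), "weight")
  empty <- withr::local_tempfile(lines = character(0))
  expect_error(read_edge_list(empty), "empty")
})

test_that("duplicate links load identically to a single summed link downstream", {
  fa <- withr::local_tempfile(lines = c("1 2 1", "1 2 1", "1 2 2", "2 3 1", "3 1 1"))
  fb <- withr::local_tempfile(lines = c("1 2 4", "2 3 1", "3 1 1"))
  fla <- network_flow(read_edge_list(fa))
  flb <- network_flow(read_edge_list(fb))
  expect_equal(two_level_codelength(fla, c(1, 1, 2))$total_bits,
               two_level_codelength(flb, c(1, 1, 2))$total_bits,
               tolerance = 1e-14)
})

test_that("Pajek files parse with *Edges undirected and *Arcs directed", {
  f <- withr::local_tempfile(lines = c("*Vertices 2", "1 \"u\"", "2 \"v\"",
                                       "*Edges", "1 2 1"))
  net <- read_pajek(f)
  expect_false(net$directed)
  expect_equal(net$n_nodes, 2L)
  expect_equal(nrow(net$links), 1L)
  expect_equal(net$node_names, c("u", "v"))

  fa <- withr::local_tempfile(lines = c("*Vertices 2", "1 \"u\"", "2 \"v\"",
                                        "*Arcs", "1 2 1"))
  expect_true(read_pajek(fa)$directed)

  noheader <- withr::local_tempfile(lines = c("1 2"))
  expect_error(read_pajek(noheader), "Vertices")
})

test_that("write/read round trips are identity on the 27-node example", {
  fx <- triangle_hierarchy_network()
  f <- withr::local_tempfile()
  write_pajek(fx$network, f)
  back <- read_pajek(f)
  expect_equal(back$n_nodes, fx$network$n_nodes)
  expect_equal(back$directed, fx$network$directed)
  expect_equal(back$links[order(back$links$from, back$links$to), ],
               fx$network$links[order(fx$network$links$from,
                                      fx$network$links$to), ],
               ignore_attr = TRUE)
  expect_equal(back$node_names, fx$network$node_names)

  f2 <- withr::local_tempfile()
  write_edge_list(fx$network, f2, use_names = FALSE)
  back2 <- read_edge_list(f2)
  expect_equal(sum(node_strength(back2)), 78)
  expect_equal(nrow(back2$links), 39L)
})

test_that("network construction validates ranges and keeps self-loops", {
  expect_error(flow_network(data.frame(from = 1, to = 5, weight = 1),
                            n_nodes = 3), "out of range")
  expect_error(flow_network(data.frame(from = 1, to = 2, weight = -1)),
               "positive")
  withself <- flow_network(data.frame(from = c(1, 1), to = c(1, 2)),
                           n_nodes = 2)
  expect_equal(nrow(withself$links), 2L)
  # self-loop counts twice in undirected strength
  expect_equal(node_strength(withself), c(3, 1))
})
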