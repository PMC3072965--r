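# Visit rates, teleportation exclusion, boundary rates.

test_that("undirected visit rates are strength-proportional in closed form", {
  fx <- triangle_hierarchy_network()
  fl <- ergodic_visit_rates(fx$network)
  s <- node_strength(fx$network)
  expect_equal(fl$node_rate, s / 78, tolerance = 1e-15)
  expect_setequal(round(unique(fl$node_rate) * 78), c(2, 3))
  expect_equal(sum(fl$node_rate), 1, tolerance = 1e-10)
  # corrected field is the raw field for undirected networks
  cor <- exclude_teleportation(fx$network, fl)
  expect_true(cor$corrected)
  expect_equal(cor$node_rate, fl$node_rate)
  expect_equal(sum(cor$links$flow), 1, tolerance = 1e-10)
})

test_that("directed 2-cycle has symmetric rates for any teleport rate", {
  net <- flow_network(data.frame(from = c(1, 2), to = c(2, 1)),
                      directed = TRUE)
  for (tau in c(0, 0.15, 0.5)) {
    fl <- ergodic_visit_rates(net, teleport_rate = tau)
    expect_equal(fl$node_rate, c(0.5, 0.5), tolerance = 1e-10)
    cor <- exclude_teleportation(net, fl)
    expect_equal(cor$links$flow, c(0.5, 0.5), tolerance = 1e-10)
  }
})

test_that("directed star matches a dense eigenvector oracle", {
  k <- 6
  net <- flow_network(data.frame(from = c(2:(k + 1), rep(1, k)),
                                 to = c(rep(1, k), 2:(k + 1))),
                      directed = TRUE)
  fl <- ergodic_visit_rates(net, teleport_rate = 0.15)
  expect_equal(fl$node_rate, eigen_stationary(net, 0.15), tolerance = 1e-9)
})

test_that("teleportation exclusion on a directed chain matches hand computation", {
  net <- flow_network(data.frame(from = c(1, 2), to = c(2, 3)),
                      directed = TRUE)
  tau <- 0.15
  fl <- ergodic_visit_rates(net, tau)
  p <- eigen_stationary(net, tau)
  expect_equal(fl$node_rate, p, tolerance = 1e-9)
  # link-following probabilities: node 3 is dangling
  q <- c(p[1] * (1 - tau), p[2] * (1 - tau))
  cor <- exclude_teleportation(net, fl)
  expect_equal(cor$links$flow, q / sum(q), tolerance = 1e-9)
  # updated rates are inflow along links; node 1 receives none
  expect_equal(cor$node_rate, c(0, q[1], q[2]) / sum(q), tolerance = 1e-9)
})

test_that("power iteration reports non-convergence with the residual", {
  net <- flow_network(data.frame(from = c(1, 2), to = c(2, 1)),
                      directed = TRUE)
  expect_error(ergodic_visit_rates(net, 0.15, tol = 0, max_iter = 3L),
               "converge")
})

test_that("undirected closed form equals power iteration run directly", {
  withr::local_seed(7)
  net <- random_connected_graph(12, 0.3)
  fl <- network_flow(net)
  # run the directed machinery on the symmetrized link set
  l <- net$links
  dir_net <- flow_network(data.frame(from = c(l$from, l$to),
                                     to = c(l$to, l$from),
                                     weight = c(l$weight, l$weight)),
                          n_nodes = net$n_nodes, directed = TRUE)
  it <- ergodic_visit_rates(dir_net, teleport_rate = 0, tol = 1e-14)
  expect_equal(fl$node_rate, it$node_rate, tolerance = 1e-9)
})

test_that("increasing a link weight never decreases that link's flow", {
  withr::local_seed(11)
  net <- random_connected_graph(10, 0.3)
  fl <- network_flow(net)
  for (i in c(1L, 3L, 5L)) {
    l2 <- net$links
    l2$weight[i] <- l2$weight[i] + 1
    net2 <- flow_network(l2, n_nodes = net$n_nodes)
    fl2 <- network_flow(net2)
    pick <- function(f, a, b) f$links$flow[f$links$from == a & f$links$to == b]
    expect_gte(pick(fl2, net$links$from[i], net$links$to[i]),
               pick(fl, net$links$from[i], net$links$to[i]))
  }
})

test_that("module boundary rates count crossing links on the worked example", {
  fx <- triangle_hierarchy_network()
  fl <- network_flow(fx$network)
  br <- module_boundary_rates(fl, as_hpartition(fx$triangles))
  # six triangles carry 3 external links, three carry 2; undirected: enter = exit
  expect_equal(sort(round(br$exit * 78)), c(rep(2, 3), rep(3, 6)))
  expect_equal(br$enter, br$exit, tolerance = 1e-12)
  # single module of a connected network has no boundary flow
  br1 <- module_boundary_rates(fl, as_hpartition(rep(1, 27)))
  expect_equal(br1$enter, 0)
  expect_equal(br1$exit, 0)
})

test_that("sibling enter rates plus parent exit equal the parent codebook use", {
  fx <- triangle_hierarchy_network()
  fl <- network_flow(fx$network)
  rep3 <- hierarchical_codelength(fl, fx$partition)
  v <- rep3$vertices
  for (par in v$path[v$level == 1]) {
    children <- v[v$level == 2 & startsWith(v$path, paste0(par, ":")), ]
    parent <- v[v$path == par, ]
    expect_equal(parent$use_rate, sum(children$enter) + parent$exit,
                 tolerance = 1e-12)
  }
})

test_that("flow validation rejects mismatched node sets and bad inputs", {
  fx <- triangle_hierarchy_network()
  fl <- network_flow(fx$network)
  expect_error(module_boundary_rates(fl, as_hpartition(rep(1, 5))), "27")
  raw <- ergodic_visit_rates(fx$network)
  raw$node_rate <- raw$node_rate * 2
  expect_error(exclude_teleportation(fx$network, raw), "normalized")
  expect_error(ergodic_visit_rates(flow_network(
    data.frame(from = 1, to = 2), n_nodes = 2, directed = TRUE),
    teleport_rate = 1), "teleport")
})
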