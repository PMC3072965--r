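# Shared fixtures and independent oracles for the test suite.

# two disconnected unit triangles on 6 nodes
two_triangles <- function() {
  flow_network(data.frame(from = c(1, 1, 2, 4, 4, 5),
                          to   = c(2, 3, 3, 5, 6, 6)),
               n_nodes = 6)
}

complete_graph <- function(n) {
  e <- t(utils::combn(n, 2))
  flow_network(data.frame(from = e[, 1], to = e[, 2]), n_nodes = n)
}

path_graph <- function(n) {
  flow_network(data.frame(from = seq_len(n - 1), to = 2:n), n_nodes = n)
}

# random connected undirected graph: random spanning tree plus extra edges
random_connected_graph <- function(n, extra_p = 0.3) {
  to <- 2:n
  from <- vapply(to, function(v) sample.int(v - 1L, 1L), integer(1))
  edges <- cbind(from, to)
  all_pairs <- t(utils::combn(n, 2))
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  rest <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% key), ,
                    drop = FALSE]
  add <- rest[stats::runif(nrow(rest)) < extra_p, , drop = FALSE]
  edges <- rbind(edges, add)
  flow_network(data.frame(from = edges[, 1], to = edges[, 2]), n_nodes = n)
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxval) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(maxval + 1L)) rec(c(prefix, v), max(maxval, v))
  }
  rec(integer(0), 0L)
  out
}

# independent oracle: minimum two-level codelength by exhaustive enumeration
brute_force_min_two_level <- function(flow, partitions = NULL) {
  if (is.null(partitions)) partitions <- all_set_partitions(flow$n_nodes)
  best <- Inf
  best_mem <- NULL
  for (mem in partitions) {
    b <- two_level_codelength(flow, mem)$total_bits
    if (b < best) { best <- b; best_mem <- mem }
  }
  list(bits = best, membership = best_mem)
}

# independent oracle: minimum hierarchical codelength over all depth <= 3
# trees (every flat partition, every grouping of its modules)
brute_force_min_hierarchy <- function(flow) {
  best <- Inf
  for (mem in all_set_partitions(flow$n_nodes)) {
    m <- max(mem)
    for (grp in all_set_partitions(m)) {
      hp <- hpartition(lapply(seq_along(mem),
                              function(u) c(grp[mem[u]], mem[u])))
      b <- hierarchical_codelength(flow, hp)$total_bits
      if (b < best) best <- b
    }
  }
  best
}

# dense stationary-distribution oracle for the teleporting directed walk
eigen_stationary <- function(net, tau) {
  n <- net$n_nodes
  W <- matrix(0, n, n)
  for (i in seq_len(nrow(net$links)))
    W[net$links$from[i], net$links$to[i]] <-
      W[net$links$from[i], net$links$to[i]] + net$links$weight[i]
  s <- rowSums(W)
  P <- matrix(1 / n, n, n)
  ok <- s > 0
  P[ok, ] <- W[ok, , drop = FALSE] / s[ok]
  G <- (1 - tau) * P + tau * matrix(1 / n, n, n)
  # dangling rows already teleport uniformly through P
  G[!ok, ] <- (1 - tau) / n + tau / n
  ev <- eigen(t(G))
  v <- Re(ev$vectors[, which.max(Re(ev$values))])
  v / sum(v)
}

# every isomorphism class of connected graphs on n nodes (n small), via
# labeled enumeration and igraph canonical forms
connected_graph_classes <- function(n) {
  pairs <- t(utils::combn(n, 2))
  np <- nrow(pairs)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (mask in seq_len(2^np) - 1L) {
    sel <- bitwAnd(mask, 2^(seq_len(np) - 1L)) > 0L
    if (sum(sel) < n - 1L) next
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(pairs[sel, , drop = FALSE]))
    if (!igraph::is_connected(g)) next
    cp <- igraph::canonical_permutation(g)$labeling
    cg <- igraph::permute(g, cp)
    cel <- igraph::as_edgelist(cg)
    key <- paste(sort(paste(pmin(cel[, 1], cel[, 2]),
                            pmax(cel[, 1], cel[, 2]))), collapse = ";")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      el <- pairs[sel, , drop = FALSE]
      out[[length(out) + 1L]] <-
        flow_network(data.frame(from = el[, 1], to = el[, 2]), n_nodes = n)
    }
  }
  out
}
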