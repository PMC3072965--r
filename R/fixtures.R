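# Deterministic nested-clique example networks.
#
# The family generalizes a classic hierarchical test network: cliques of size
# k are joined in rings of b by single unit-weight links, ring groups are in
# turn joined in rings of b, and so on for `levels` levels. Every ring link
# attaches to a node that carries no other ring link ("ports"), so the degree
# sequence is pinned exactly: with (3, 3, 3) this yields the 27-node network
# with 39 links, total degree 78, and 24 nodes of degree 3 plus 3 of degree 2.

#' Nested-clique hierarchical network
#'
#' @param clique_size Nodes per clique (k >= 2).
#' @param branching Units joined in a ring at each higher level (b >= 2).
#' @param levels Number of hierarchy levels including the clique level
#'   (`levels = 1` returns a single clique).
#' @return A `flownet`. The construction is deterministic: repeated calls give
#'   byte-identical edge lists.
#' @examples
#' nested_clique_network(3, 3, 2)  # 3 triangles in a ring, 12 links
#' @export
nested_clique_network <- function(clique_size, branching, levels) {
  k <- as.integer(clique_size); b <- as.integer(branching)
  L <- as.integer(levels)
  if (k < 2L) stop_validation("clique_size must be at least 2")
  if (L < 1L) stop_validation("levels must be at least 1")
  if (L > 1L && b < 2L) stop_validation("branching must be at least 2")
  n_cliques <- b^(L - 1L)
  n <- k * n_cliques
  edges <- do.call(rbind, lapply(seq_len(n_cliques), function(ci) {
    base <- (ci - 1L) * k
    idx <- utils::combn(k, 2)
    cbind(base + idx[1, ], base + idx[2, ])
  }))
  # units carry their unused ports (nodes without a ring link yet)
  units <- lapply(seq_len(n_cliques), function(ci)
    list(ports = (ci - 1L) * k + seq_len(k)))
  for (lev in seq_len(L)[-1L]) {
    next_units <- list()
    groups <- split(seq_along(units),
                    rep(seq_len(length(units) / b), each = b))
    for (g in groups) {
      members <- units[g]
      for (j in seq_len(b)) {
        jn <- if (j == b) 1L else j + 1L
        if (length(members[[j]]$ports) < 1L ||
            length(members[[jn]]$ports) < (if (jn == j) 2L else 1L))
          stop_validation("overfull link placement: not enough free ports")
        out_port <- members[[j]]$ports[1L]
        members[[j]]$ports <- members[[j]]$ports[-1L]
        in_port <- members[[jn]]$ports[1L]
        members[[jn]]$ports <- members[[jn]]$ports[-1L]
        edges <- rbind(edges, c(out_port, in_port))
      }
      next_units[[length(next_units) + 1L]] <-
        list(ports = unlist(lapply(members, `[[`, "ports")))
    }
    units <- next_units
  }
  flow_network(data.frame(from = edges[, 1], to = edges[, 2], weight = 1),
               n_nodes = n, directed = FALSE,
               node_names = as.character(seq_len(n)))
}

#' The 27-node worked-example network and its reference hierarchy
#'
#' Nine triangles; within each group of three, triangles joined in a ring by
#' single links; the three groups joined in a ring by single links, each ring
#' link landing on a node with no other extra link. Total degree 78. The
#' reference partition is the three-level hierarchy (3 supermodules of 3
#' triangles of 3 nodes); its finest slice is the nine-triangle flat
#' partition.
#'
#' @return A list with elements `network` (a `flownet`), `partition` (the
#'   depth-3 reference `hpartition`) and `triangles` (the flat nine-triangle
#'   membership vector).
#' @examples
#' fx <- triangle_hierarchy_network()
#' sum(node_strength(fx$network))  # total degree 78
#' @export
triangle_hierarchy_network <- function() {
  net <- nested_clique_network(3, 3, 3)
  triangle <- rep(seq_len(9L), each = 3L)
  group <- rep(seq_len(3L), each = 9L)
  paths <- mapply(function(g, t) c(g, ((t - 1L) %% 3L) + 1L),
                  group, triangle, SIMPLIFY = FALSE)
  list(network = net,
       partition = hpartition(paths, node_names = net$node_names),
       triangles = triangle)
}
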