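# Random-walk flow on a network.
#
# The map equation describes a random walker moving along links. For
# undirected networks the stationary visit rate of a node is proportional to
# its strength, in closed form. For directed networks ergodicity is enforced
# by uniform teleportation at rate tau, and the description length afterwards
# excludes the teleportation steps: only link-following flow is described
# (link-following probability from the ergodic rates, then visit rates updated
# to the inflow along links and renormalized so that all described events sum
# to one per step).

#' Ergodic visit rates of the (teleporting) random walker
#'
#' For undirected networks the stationary distribution is
#' `strength / total strength` exactly and no iteration is run; the teleport
#' rate plays no role. For directed networks the stationary distribution of
#' the walk with uniform teleportation at rate `teleport_rate` is computed by
#' power iteration; dangling nodes (no out-links) teleport uniformly.
#'
#' @param net A `flownet`.
#' @param teleport_rate Teleportation probability per step, in `[0, 1)`.
#'   Ignored for undirected networks.
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter Maximum number of iterations.
#' @return A `flowfield`: `node_rate` (visit rate per node), `links` (directed
#'   rows `from`, `to`, `flow`; for undirected networks both directions of each
#'   link are present), `teleport_rate`, `directed`, and `corrected = FALSE`
#'   (raw ergodic dynamics).
#' @export
ergodic_visit_rates <- function(net, teleport_rate = 0.15, tol = 1e-12,
                                max_iter = 10000L) {
  if (!inherits(net, "flownet")) stop_validation("net must be a flownet")
  if (net$n_nodes < 1L || nrow(net$links) == 0L)
    stop_validation("empty network")
  l <- net$links
  if (!net$directed) {
    s <- node_strength(net)
    total <- sum(s)
    p <- s / total
    self <- l$from == l$to
    links <- data.frame(
      from = c(l$from[!self], l$to[!self], l$from[self]),
      to   = c(l$to[!self], l$from[!self], l$to[self]),
      flow = c(l$weight[!self], l$weight[!self], 2 * l$weight[self]) / total)
    return(structure(list(n_nodes = net$n_nodes, node_rate = p, links = links,
                          teleport_rate = NA_real_, directed = FALSE,
                          corrected = FALSE, node_names = net$node_names),
                     class = "flowfield"))
  }
  tau <- teleport_rate
  if (tau < 0 || tau >= 1)
    stop_validation("teleport_rate must be in [0, 1)")
  n <- net$n_nodes
  s <- node_strength(net)  # out-strength
  dangling <- s == 0
  rel_w <- l$weight / s[l$from]
  # transposed transition structure for p %*% P via sparse matvec
  P_t <- Matrix::sparseMatrix(i = l$to, j = l$from, x = rel_w, dims = c(n, n))
  p <- rep(1 / n, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    follow <- as.numeric(P_t %*% p)
    dang_mass <- sum(p[dangling])
    p_new <- (1 - tau) * follow + ((1 - tau) * dang_mass + tau) / n
    resid <- sum(abs(p_new - p))
    p <- p_new
    if (resid < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("power iteration did not converge in %d iterations (L1 residual %.3e)",
                 max_iter, resid), call. = FALSE)
  links <- data.frame(from = l$from, to = l$to,
                      flow = p[l$from] * (1 - tau) * rel_w)
  structure(list(n_nodes = n, node_rate = p, links = links,
                 teleport_rate = tau, directed = TRUE, corrected = FALSE,
                 node_names = net$node_names),
            class = "flowfield")
}

#' Exclude teleportation steps from the described dynamics
#'
#' Per-link flow is the probability that the walker, at its ergodic rate, does
#' not teleport but follows that specific link. Flows are renormalized to sum
#' to one, and node visit rates are updated to the total inflow along links
#' into each node (in- and outflow of a node need no longer be equal). For
#' undirected networks teleportation plays no role and the field is returned
#' unchanged apart from the `corrected` flag.
#'
#' @param net The `flownet` the field was computed on.
#' @param raw A raw ergodic `flowfield` from [ergodic_visit_rates()].
#' @return A corrected `flowfield` whose link flows sum to 1.
#' @export
exclude_teleportation <- function(net, raw) {
  if (!inherits(raw, "flowfield")) stop_validation("raw must be a flowfield")
  if (raw$n_nodes != net$n_nodes)
    stop_validation("flow field and network disagree on the node count")
  if (abs(sum(raw$node_rate) - 1) > 1e-8)
    stop_validation("raw visit rates are not normalized")
  out <- raw
  if (!raw$directed) {
    out$corrected <- TRUE
    return(out)
  }
  phi <- raw$links$flow
  total <- sum(phi)
  if (total <= 0) stop_validation("no link-following flow on this network")
  phi <- phi / total
  p <- numeric(raw$n_nodes)
  inflow <- rowsum(phi, raw$links$to)
  p[as.integer(rownames(inflow))] <- inflow
  out$links$flow <- phi
  out$node_rate <- p
  out$corrected <- TRUE
  out
}

#' Compute corrected random-walk flow in one call
#'
#' Convenience wrapper: [ergodic_visit_rates()] followed by
#' [exclude_teleportation()].
#' @inheritParams ergodic_visit_rates
#' @return A corrected `flowfield`.
#' @export
network_flow <- function(net, teleport_rate = 0.15, tol = 1e-12,
                         max_iter = 10000L) {
  exclude_teleportation(net, ergodic_visit_rates(net, teleport_rate, tol,
                                                 max_iter))
}

#' @export
print.flowfield <- function(x, ...) {
  cat(sprintf("<flowfield> %d nodes, %d directed flow entries, %s%s\n",
              x$n_nodes, nrow(x$links),
              if (x$corrected) "teleportation-excluded" else "raw ergodic",
              if (x$directed) sprintf(" (tau = %g)", x$teleport_rate) else ""))
  invisible(x)
}

#' Per-module enter and exit rates of a hierarchical partition
#'
#' For every module vertex at every depth, the rate at which the walker
#' crosses into the module from outside (`enter`) and out of it (`exit`).
#' For undirected networks enter equals exit for every module.
#'
#' @param flow A corrected `flowfield`.
#' @param partition An `hpartition` over the same nodes.
#' @return A data frame with one row per module vertex: `path`, `level`,
#'   `flow` (total visit rate of member nodes), `enter`, `exit`, `n_nodes`.
#' @export
module_boundary_rates <- function(flow, partition) {
  ann <- annotate_partition(flow, partition)
  ann$vertices[, c("path", "level", "flow", "enter", "exit", "n_nodes")]
}

# Shared annotation: per-vertex flow, enter, exit, children bookkeeping.
#' @keywords internal
#' @noRd
annotate_partition <- function(flow, partition) {
  if (!inherits(flow, "flowfield")) stop_validation("flow must be a flowfield")
  if (!isTRUE(flow$corrected))
    stop_validation("flow must be teleportation-corrected (see network_flow)")
  if (!inherits(partition, "hpartition"))
    stop_validation("partition must be an hpartition")
  if (partition$n_nodes != flow$n_nodes)
    stop_validation("partition covers %d nodes but the flow field has %d",
                    partition$n_nodes, flow$n_nodes)
  paths <- partition$paths
  depth <- lengths(paths)
  maxd <- max(depth)
  # level-k ancestor keys per node (NA above the node's finest module)
  keys <- lapply(seq_len(maxd), function(k) path_keys(paths, k))
  vertex_ids <- lapply(seq_len(maxd), function(k) unique(keys[[k]][!is.na(keys[[k]])]))
  l <- flow$links
  enter <- list()
  exit <- list()
  for (k in seq_len(maxd)) {
    ka <- keys[[k]][l$from]
    kb <- keys[[k]][l$to]
    a_in <- !is.na(ka)
    b_in <- !is.na(kb)
    crossing <- (a_in & !b_in) | (b_in & !a_in) |
      (a_in & b_in & ka != kb)
    ex <- rowsum(l$flow[crossing & a_in], ka[crossing & a_in])
    en <- rowsum(l$flow[crossing & b_in], kb[crossing & b_in])
    exit_k <- structure(numeric(length(vertex_ids[[k]])),
                        names = vertex_ids[[k]])
    enter_k <- exit_k
    exit_k[rownames(ex)] <- ex
    enter_k[rownames(en)] <- en
    exit[[k]] <- exit_k
    enter[[k]] <- enter_k
  }
  vertices <- do.call(rbind, lapply(seq_len(maxd), function(k) {
    ids <- vertex_ids[[k]]
    member <- !is.na(keys[[k]])
    fl <- structure(numeric(length(ids)), names = ids)
    fsum <- rowsum(flow$node_rate[member], keys[[k]][member])
    fl[rownames(fsum)] <- fsum
    cnt <- table(keys[[k]][member])
    data.frame(path = ids, level = k, flow = as.numeric(fl),
               enter = as.numeric(enter[[k]]), exit = as.numeric(exit[[k]]),
               n_nodes = as.integer(cnt[ids]), stringsAsFactors = FALSE)
  }))
  rownames(vertices) <- NULL
  list(vertices = vertices, keys = keys, depth = depth)
}
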