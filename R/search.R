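# Stochastic recursive minimization of the (hierarchical) map equation.
#
# The optimizer works on "contexts". A context is the content of one module:
# movable units (initially nodes), their codeword rates p, the directed link
# flows among them, per-unit flows crossing the context boundary, and the
# context's own exit rate e (the rate of the "move up" codeword in its index
# codebook). The flat objective inside a context is
#
#   L = [plogp(e + Q) - plogp(e) - sum_m plogp(enter_m)]
#     + sum_m [plogp(exit_m + p_m) - plogp(exit_m)] - sum_u plogp(p_u)
#
# with Q = sum_m enter_m: the index codebook over child enter rates plus the
# up-move, and one codebook per child module. Describing the context as a
# single undivided module costs plogp(e + P) - plogp(e) - sum_u plogp(p_u).
#
# The same machinery searches for coarser levels: aggregate the current
# modules into units whose rate p is their enter rate, and the "module
# codebooks" of that aggregate problem become subindex codebooks over the
# enter rates of member modules plus the group exit - exactly the
# intermediate-level terms of the hierarchical map equation. The recursion
# therefore only needs one engine, applied both to the networks within
# modules (finer levels) and to the network formed by the modules (coarser
# levels), keeping extra index codebooks only when they shorten the total
# description. Flow is computed once on the full network; all aggregate moves
# operate on summed rates and boundary flows, which aggregate exactly.

# ---- context construction -------------------------------------------------

#' @keywords internal
#' @noRd
make_context <- function(p, links, ext_in = NULL, ext_out = NULL) {
  np <- length(p)
  if (is.null(ext_in)) ext_in <- numeric(np)
  if (is.null(ext_out)) ext_out <- numeric(np)
  keep <- links$from != links$to
  links <- links[keep, , drop = FALSE]
  out_tot <- numeric(np); in_tot <- numeric(np)
  adj_nb <- vector("list", np)
  adj_out <- vector("list", np)
  adj_in <- vector("list", np)
  if (nrow(links)) {
    ot <- rowsum(links$flow, links$from)
    it <- rowsum(links$flow, links$to)
    out_tot[as.integer(rownames(ot))] <- ot
    in_tot[as.integer(rownames(it))] <- it
    # combined neighbor lists with out/in flow per neighbor
    ends <- c(links$from, links$to)
    other <- c(links$to, links$from)
    wout <- c(links$flow, numeric(nrow(links)))
    win <- c(numeric(nrow(links)), links$flow)
    o <- order(ends, other)
    ends <- ends[o]; other <- other[o]; wout <- wout[o]; win <- win[o]
    key <- (ends - 1) * as.double(np) + other
    grp <- !duplicated(key)
    idx <- cumsum(grp)
    u_ends <- ends[grp]; u_other <- other[grp]
    u_wout <- as.numeric(rowsum(wout, idx, reorder = FALSE))
    u_win <- as.numeric(rowsum(win, idx, reorder = FALSE))
    split_idx <- split(seq_along(u_ends), u_ends)
    for (nm in names(split_idx)) {
      i <- split_idx[[nm]]
      u <- as.integer(nm)
      adj_nb[[u]] <- u_other[i]
      adj_out[[u]] <- u_wout[i]
      adj_in[[u]] <- u_win[i]
    }
  }
  list(np = np, p = p, links = links,
       adj_nb = adj_nb, adj_out = adj_out, adj_in = adj_in,
       out_tot = out_tot, in_tot = in_tot,
       ext_in = ext_in, ext_out = ext_out,
       e = sum(ext_out), const_plogp = sum(plogp(p)))
}

#' @keywords internal
#' @noRd
context_from_flow <- function(flow) {
  make_context(flow$node_rate, flow$links)
}

# Bits to describe the context's content as one undivided module.
#' @keywords internal
#' @noRd
leaf_bits <- function(ctx) {
  plogp(ctx$e + sum(ctx$p)) - plogp(ctx$e) - ctx$const_plogp
}

# Bits to describe the context's content under a flat partition of its units.
#' @keywords internal
#' @noRd
context_partition_bits <- function(ctx, mem) {
  mem <- as.integer(factor(mem, levels = unique(mem)))
  p_m <- as.numeric(rowsum(ctx$p, mem))
  m <- length(p_m)
  if (m == 1L) return(leaf_bits(ctx))
  exit <- as.numeric(rowsum(ctx$ext_out, mem))
  enter <- as.numeric(rowsum(ctx$ext_in, mem))
  l <- ctx$links
  if (nrow(l)) {
    ma <- mem[l$from]; mb <- mem[l$to]
    cr <- ma != mb
    if (any(cr)) {
      ex <- rowsum(l$flow[cr], ma[cr]); en <- rowsum(l$flow[cr], mb[cr])
      exit[as.integer(rownames(ex))] <- exit[as.integer(rownames(ex))] + ex
      enter[as.integer(rownames(en))] <- enter[as.integer(rownames(en))] + en
    }
  }
  (plogp(ctx$e + sum(enter)) - plogp(ctx$e) - sum(plogp(enter))) +
    sum(plogp(exit + p_m) - plogp(exit)) - ctx$const_plogp
}

# ---- greedy local moves ---------------------------------------------------

#' @keywords internal
#' @noRd
new_move_state <- function(ctx, mem = NULL) {
  np <- ctx$np
  if (is.null(mem)) mem <- seq_len(np)
  mem <- as.integer(factor(mem, levels = unique(mem)))
  p_m <- numeric(np); exit <- numeric(np); enter <- numeric(np)
  nmem <- integer(np)
  agg_p <- rowsum(ctx$p, mem)
  p_m[as.integer(rownames(agg_p))] <- agg_p
  agg_eo <- rowsum(ctx$ext_out, mem); agg_ei <- rowsum(ctx$ext_in, mem)
  exit[as.integer(rownames(agg_eo))] <- agg_eo
  enter[as.integer(rownames(agg_ei))] <- agg_ei
  l <- ctx$links
  if (nrow(l)) {
    ma <- mem[l$from]; mb <- mem[l$to]
    cr <- ma != mb
    if (any(cr)) {
      ex <- rowsum(l$flow[cr], ma[cr]); en <- rowsum(l$flow[cr], mb[cr])
      exit[as.integer(rownames(ex))] <- exit[as.integer(rownames(ex))] + ex
      enter[as.integer(rownames(en))] <- enter[as.integer(rownames(en))] + en
    }
  }
  cnt <- table(mem)
  nmem[as.integer(names(cnt))] <- as.integer(cnt)
  env <- new.env(parent = emptyenv())
  env$mem <- mem; env$p_m <- p_m; env$exit <- exit; env$enter <- enter
  env$nmem <- nmem; env$Q <- sum(enter)
  env$free <- rev(which(nmem == 0L))
  env
}

# One randomized sequential pass over all units; returns the number of moves.
# Tie-breaking: a unit stays put unless some move strictly decreases the
# codelength by more than thr; among equal best decreases the lowest-numbered
# candidate module wins (candidates are scanned in increasing id order).
#' @keywords internal
#' @noRd
move_sweep <- function(ctx, st, thr) {
  np <- ctx$np
  moves <- 0L
  e <- ctx$e
  for (u in sample.int(np)) {
    a <- st$mem[u]
    nb <- ctx$adj_nb[[u]]
    if (is.null(nb) && st$nmem[a] <= 1L) next
    if (length(nb)) {
      mm <- st$mem[nb]
      agg <- rowsum(cbind(ctx$adj_out[[u]], ctx$adj_in[[u]]), mm)
      cand <- as.integer(rownames(agg))
      k_out <- agg[, 1]; k_in <- agg[, 2]
    } else {
      cand <- integer(0); k_out <- numeric(0); k_in <- numeric(0)
    }
    ka <- match(a, cand)
    k_out_a <- if (is.na(ka)) 0 else k_out[ka]
    k_in_a <- if (is.na(ka)) 0 else k_in[ka]
    # allow splitting off into a fresh module
    if (st$nmem[a] > 1L && length(st$free)) {
      cand <- c(cand, st$free[length(st$free)])
      k_out <- c(k_out, 0); k_in <- c(k_in, 0)
    }
    keep <- cand != a
    cand <- cand[keep]
    if (!length(cand)) next
    k_out <- k_out[keep]; k_in <- k_in[keep]
    o <- order(cand)
    cand <- cand[o]; k_out <- k_out[o]; k_in <- k_in[o]

    p_u <- ctx$p[u]
    eo_u <- ctx$ext_out[u]; ei_u <- ctx$ext_in[u]
    ot_u <- ctx$out_tot[u]; it_u <- ctx$in_tot[u]
    enter_a <- st$enter[a]; exit_a <- st$exit[a]; p_a <- st$p_m[a]
    enter_b <- st$enter[cand]; exit_b <- st$exit[cand]; p_b <- st$p_m[cand]

    exit_a2 <- exit_a - eo_u - (ot_u - k_out_a) + k_in_a
    enter_a2 <- enter_a - ei_u - (it_u - k_in_a) + k_out_a
    exit_b2 <- exit_b + eo_u + (ot_u - k_out) - k_in
    enter_b2 <- enter_b + ei_u + (it_u - k_in) - k_out
    Q2 <- st$Q + (enter_a2 - enter_a) + (enter_b2 - enter_b)

    delta <- (plogp(e + Q2) - plogp(e + st$Q)) -
      (plogp(enter_a2) + plogp(enter_b2) -
         plogp(enter_a) - plogp(enter_b)) +
      (plogp(exit_a2 + p_a - p_u) - plogp(exit_a2) +
         plogp(exit_b2 + p_b + p_u) - plogp(exit_b2)) -
      (plogp(exit_a + p_a) - plogp(exit_a) +
         plogp(exit_b + p_b) - plogp(exit_b))

    best <- which.min(delta)
    if (delta[best] < -thr) {
      b <- cand[best]
      st$mem[u] <- b
      st$p_m[a] <- p_a - p_u; st$p_m[b] <- p_b[best] + p_u
      st$exit[a] <- exit_a2; st$enter[a] <- enter_a2
      st$exit[b] <- exit_b2[best]; st$enter[b] <- enter_b2[best]
      st$Q <- st$Q + (enter_a2 - enter_a) + (enter_b2[best] - enter_b[best])
      st$nmem[a] <- st$nmem[a] - 1L
      st$nmem[b] <- st$nmem[b] + 1L
      if (length(st$free) && b == st$free[length(st$free)])
        st$free <- st$free[-length(st$free)]
      if (st$nmem[a] == 0L) st$free <- c(st$free, a)
      moves <- moves + 1L
    }
  }
  moves
}

#' @keywords internal
#' @noRd
sweep_to_convergence <- function(ctx, st, thr, max_sweeps = 200L) {
  for (i in seq_len(max_sweeps)) {
    if (move_sweep(ctx, st, thr) == 0L) break
  }
  invisible(NULL)
}

#' @keywords internal
#' @noRd
aggregate_context <- function(ctx, mem) {
  mem <- as.integer(factor(mem, levels = unique(mem)))
  p <- as.numeric(rowsum(ctx$p, mem))
  ext_in <- as.numeric(rowsum(ctx$ext_in, mem))
  ext_out <- as.numeric(rowsum(ctx$ext_out, mem))
  l <- ctx$links
  if (nrow(l)) {
    mf <- mem[l$from]; mt <- mem[l$to]
    key <- (mf - 1) * as.double(length(p)) + mt
    fl <- rowsum(l$flow, key, reorder = FALSE)
    keep <- !duplicated(key)
    links <- data.frame(from = mf[keep], to = mt[keep],
                        flow = as.numeric(fl))
  } else {
    links <- l
  }
  c2 <- make_context(p, links, ext_in, ext_out)
  c2$const_plogp <- ctx$const_plogp  # node-level constant carries through
  c2
}

# Louvain-style core: greedy sweeps, then rebuild the network with modules as
# nodes, repeating until no rebuild improves. Returns the membership of the
# original units.
#' @keywords internal
#' @noRd
core_flat <- function(ctx, thr, init = NULL) {
  cur <- ctx
  mem_total <- NULL
  st <- new_move_state(cur, mem = init)  # NULL init = singletons
  repeat {
    sweep_to_convergence(cur, st, thr)
    mem <- as.integer(factor(st$mem, levels = unique(st$mem)))
    mem_total <- if (is.null(mem_total)) mem else mem[mem_total]
    if (max(mem) == cur$np) break      # nothing merged at this level
    cur <- aggregate_context(cur, mem)
    if (cur$np == 1L) break
    st <- new_move_state(cur)
  }
  mem_total
}

# Recursively split the units of one module, ignoring everything outside it
# ("each cluster is treated as a network on its own"), to obtain freely
# movable submodules.
#' @keywords internal
#' @noRd
split_recursive <- function(ctx, units, thr, depth = 0L) {
  if (length(units) <= 1L || depth > 30L) return(list(units))
  l <- ctx$links
  sel <- l$from %in% units & l$to %in% units
  sub_links <- data.frame(from = match(l$from[sel], units),
                          to = match(l$to[sel], units),
                          flow = l$flow[sel])
  iso <- make_context(ctx$p[units], sub_links)
  mem <- core_flat(iso, thr)
  if (max(mem) == 1L) return(list(units))
  out <- list()
  for (m in seq_len(max(mem))) {
    out <- c(out, split_recursive(ctx, units[mem == m], thr, depth + 1L))
  }
  out
}

#' @keywords internal
#' @noRd
refine_submodules_ctx <- function(ctx, mem, thr) {
  mem <- as.integer(factor(mem, levels = unique(mem)))
  groups <- list()
  for (m in seq_len(max(mem))) {
    groups <- c(groups, split_recursive(ctx, which(mem == m), thr))
  }
  sub_id <- integer(ctx$np)
  for (i in seq_along(groups)) sub_id[groups[[i]]] <- i
  sub_ctx <- aggregate_context(ctx, sub_id)
  init <- vapply(groups, function(g) mem[g[1]], integer(1))
  mem_sub <- core_flat(sub_ctx, thr, init = init)
  mem_sub[sub_id]
}

#' @keywords internal
#' @noRd
refine_single_nodes_ctx <- function(ctx, mem, thr) {
  core_flat(ctx, thr, init = mem)
}

# Full flat optimization of one context: core algorithm, then alternating
# submodule and single-node refinements while they improve.
#' @keywords internal
#' @noRd
optimize_flat <- function(ctx, thr, max_rounds = 20L) {
  mem <- core_flat(ctx, thr)
  bits <- context_partition_bits(ctx, mem)
  for (round in seq_len(max_rounds)) {
    m1 <- refine_submodules_ctx(ctx, mem, thr)
    m2 <- refine_single_nodes_ctx(ctx, m1, thr)
    b2 <- context_partition_bits(ctx, m2)
    if (b2 < bits - thr) {
      mem <- m2; bits <- b2
    } else break
  }
  list(mem = as.integer(factor(mem, levels = unique(mem))), bits = bits)
}

# ---- recursive multilevel construction ------------------------------------

#' @keywords internal
#' @noRd
subcontext <- function(ctx, mem, m) {
  units <- which(mem == m)
  l <- ctx$links
  from_in <- l$from %in% units
  to_in <- l$to %in% units
  internal <- from_in & to_in
  sub_links <- data.frame(from = match(l$from[internal], units),
                          to = match(l$to[internal], units),
                          flow = l$flow[internal])
  ext_out <- ctx$ext_out[units]
  ext_in <- ctx$ext_in[units]
  leaving <- from_in & !to_in
  entering <- to_in & !from_in
  if (any(leaving)) {
    ag <- rowsum(l$flow[leaving], match(l$from[leaving], units))
    ext_out[as.integer(rownames(ag))] <- ext_out[as.integer(rownames(ag))] + ag
  }
  if (any(entering)) {
    ag <- rowsum(l$flow[entering], match(l$to[entering], units))
    ext_in[as.integer(rownames(ag))] <- ext_in[as.integer(rownames(ag))] + ag
  }
  list(units = units,
       ctx = make_context(ctx$p[units], sub_links, ext_in, ext_out))
}

# Aggregate problem over the current modules, whose codeword rates are their
# enter rates: solving it decides whether coarser index codebooks pay off.
#' @keywords internal
#' @noRd
coarse_context <- function(ctx, mem) {
  mem <- as.integer(factor(mem, levels = unique(mem)))
  M <- max(mem)
  ext_in <- numeric(M); ext_out <- numeric(M)
  ag_i <- rowsum(ctx$ext_in, mem); ag_o <- rowsum(ctx$ext_out, mem)
  ext_in[as.integer(rownames(ag_i))] <- ag_i
  ext_out[as.integer(rownames(ag_o))] <- ag_o
  l <- ctx$links
  links <- data.frame(from = integer(0), to = integer(0), flow = numeric(0))
  enter <- ext_in
  if (nrow(l)) {
    mf <- mem[l$from]; mt <- mem[l$to]
    cr <- mf != mt
    if (any(cr)) {
      key <- (mf[cr] - 1) * as.double(M) + mt[cr]
      fl <- rowsum(l$flow[cr], key, reorder = FALSE)
      keep <- !duplicated(key)
      links <- data.frame(from = mf[cr][keep], to = mt[cr][keep],
                          flow = as.numeric(fl))
      en <- rowsum(links$flow, links$to)
      enter[as.integer(rownames(en))] <- enter[as.integer(rownames(en))] + en
    }
  }
  make_context(enter, links, ext_in, ext_out)
}

# Recursively describe the content of one module. Returns relative module
# paths per unit (length 0 = the unit sits directly in this module) and the
# bits this description costs given the module's boundary flows.
#' @keywords internal
#' @noRd
build_branch <- function(ctx, thr, depth, max_depth) {
  leaf <- list(paths = rep(list(integer(0)), ctx$np), bits = leaf_bits(ctx))
  if (ctx$np <= 1L || depth >= max_depth) return(leaf)
  res <- optimize_flat(ctx, thr)
  mem <- res$mem
  M <- max(mem)
  if (M <= 1L || res$bits >= leaf$bits - thr) return(leaf)
  # finer levels inside each module
  sub_paths <- vector("list", ctx$np)
  mod_bits <- numeric(M)
  for (m in seq_len(M)) {
    sc <- subcontext(ctx, mem, m)
    br <- build_branch(sc$ctx, thr, depth + 1L, max_depth)
    sub_paths[sc$units] <- br$paths
    mod_bits[m] <- br$bits
  }
  # coarser levels above the modules
  cc <- coarse_context(ctx, mem)
  cb <- build_branch(cc, thr, depth + 1L, max_depth)
  # compose: coarse path of the unit's module, the module's index within its
  # coarse group (first-appearance order), then the unit's path inside it
  ckey <- vapply(cb$paths, paste, character(1), collapse = ":")
  idx_within <- integer(M)
  for (k in unique(ckey)) {
    ms <- which(ckey == k)
    idx_within[ms] <- seq_along(ms)
  }
  paths <- lapply(seq_len(ctx$np), function(u) {
    m <- mem[u]
    c(cb$paths[[m]], idx_within[m], sub_paths[[u]])
  })
  list(paths = paths, bits = cb$bits + sum(mod_bits))
}

# ---- exported search API ---------------------------------------------------

#' Louvain-style core search for a flat partition
#'
#' Starts from singleton modules, repeatedly moves each unit (in random
#' sequential order) to the neighboring module giving the largest decrease of
#' the map equation, then rebuilds the network with modules as nodes and
#' repeats until no move improves.
#'
#' @param flow A corrected `flowfield`.
#' @param seed Optional integer seed for the random move order.
#' @param threshold Minimum codelength decrease (bits) for a move.
#' @return Integer module membership per node.
#' @export
core_partition <- function(flow, seed = NULL, threshold = 1e-10) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- context_from_flow(flow)
  as.integer(factor(core_flat(ctx, threshold)))
}

#' Submodule-movements refinement
#'
#' Each module is treated as a network on its own and recursively split into
#' submodules; the submodules, freely movable between modules, then re-enter
#' the core algorithm from the current partition. Never increases the
#' codelength.
#'
#' @inheritParams core_partition
#' @param modules Current flat membership.
#' @return Refined integer membership.
#' @export
refine_submodules <- function(flow, modules, seed = NULL, threshold = 1e-10) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- context_from_flow(flow)
  m0 <- as.integer(factor(modules, levels = unique(modules)))
  m1 <- refine_submodules_ctx(ctx, m0, threshold)
  keep_if_better(ctx, m0, m1, threshold)
}

#' Single-node-movements refinement
#'
#' Re-runs the greedy move stage with every single node freely movable,
#' starting from the current partition. Never increases the codelength.
#'
#' @inheritParams refine_submodules
#' @return Refined integer membership.
#' @export
refine_single_nodes <- function(flow, modules, seed = NULL,
                                threshold = 1e-10) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- context_from_flow(flow)
  m0 <- as.integer(factor(modules, levels = unique(modules)))
  m1 <- refine_single_nodes_ctx(ctx, m0, threshold)
  keep_if_better(ctx, m0, m1, threshold)
}

#' @keywords internal
#' @noRd
keep_if_better <- function(ctx, m0, m1, thr) {
  if (context_partition_bits(ctx, m1) <= context_partition_bits(ctx, m0) + thr)
    as.integer(factor(m1, levels = unique(m1)))
  else m0
}

#' Multilevel search minimizing the hierarchical map equation
#'
#' Best-of-`n_restarts` recursive stochastic search. Each restart finds a flat
#' partition with the core algorithm plus submodule and single-node
#' refinements, then recursively tries to add index codebooks at finer levels
#' (clustering within every module) and at coarser levels (clustering the
#' network formed by the modules), keeping extra levels only when they
#' shorten the description by more than `threshold` bits.
#'
#' @param net A `flownet`.
#' @param seed Integer seed; the search is deterministic given the seed.
#' @param n_restarts Number of independent restarts (the best result is kept).
#' @param teleport_rate Teleportation rate for directed networks.
#' @param two_level If `TRUE`, constrain the result to a flat two-level
#'   partition (no extra index codebooks).
#' @param threshold Minimum codelength improvement (bits) for accepting a
#'   move or an extra level.
#' @param max_depth Safety cap on hierarchy depth.
#' @param flow Optionally, a precomputed corrected `flowfield`.
#' @return A list with `partition` (an `hpartition`), `codelength` (bits),
#'   `report` (a `codelength_report`), and `flow`.
#' @examples
#' fx <- triangle_hierarchy_network()
#' res <- multilevel_search(fx$network, seed = 1, n_restarts = 10)
#' res$codelength  # 3.48 bits
#' @export
multilevel_search <- function(net, seed = NULL, n_restarts = 100L,
                              teleport_rate = 0.15, two_level = FALSE,
                              threshold = 1e-10, max_depth = 20L,
                              flow = NULL) {
  if (is.null(flow)) flow <- network_flow(net, teleport_rate)
  if (!is.null(seed)) set.seed(seed)
  ctx <- context_from_flow(flow)
  best_bits <- Inf
  best_paths <- NULL
  for (r in seq_len(n_restarts)) {
    if (two_level) {
      res <- optimize_flat(ctx, threshold)
      paths <- lapply(res$mem, function(m) m)
      bits <- res$bits
    } else {
      br <- build_branch(ctx, threshold, 0L, max_depth)
      paths <- br$paths
      bits <- br$bits
      if (all(lengths(paths) == 0L)) paths <- rep(list(1L), ctx$np)
    }
    if (bits < best_bits - threshold) {
      best_bits <- bits
      best_paths <- paths
    }
  }
  partition <- hpartition(best_paths, node_names = flow$node_names)
  report <- hierarchical_codelength(flow, partition)
  list(partition = partition, codelength = report$total_bits,
       report = report, flow = flow, n_restarts = n_restarts, seed = seed)
}

#' Compression gain of the multilevel over the two-level description
#'
#' Runs the two-level-constrained and the unconstrained multilevel searches
#' and returns `100 * (L2 - Lmulti) / L2`, floored at 0.
#'
#' @inheritParams multilevel_search
#' @return Percentage gain (non-negative).
#' @export
compression_gain <- function(net, seed = NULL, n_restarts = 100L,
                             teleport_rate = 0.15, threshold = 1e-10,
                             flow = NULL) {
  if (is.null(flow)) flow <- network_flow(net, teleport_rate)
  two <- multilevel_search(net, seed = seed, n_restarts = n_restarts,
                           two_level = TRUE, threshold = threshold,
                           flow = flow)
  multi <- multilevel_search(net, seed = seed, n_restarts = n_restarts,
                             threshold = threshold, flow = flow)
  max(0, 100 * (two$codelength - multi$codelength) / two$codelength)
}
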