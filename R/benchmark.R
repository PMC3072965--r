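# Synthetic three-level benchmark networks.
#
# Scale-free networks with planted coarse modules and fine submodules: each
# node's links are split into three pools - a fraction mu1 to nodes in other
# coarse modules, mu2 to nodes in other fine modules of the same coarse
# module, and the remaining 1 - mu1 - mu2 inside its own fine module. Degrees
# follow a truncated power law, module sizes at both levels follow truncated
# power laws, and stubs are matched configuration-model style within each
# pool with rewiring to remove self-loops, multi-edges and wrong-pool pairs.
#
# The hierarchy is topologically well defined when the per-available-pair
# link densities are ordered: within-fine > within-coarse-between-fine >
# between-coarse. With the available-link approximations n_f*k, (n_c-n_f)*k
# and (N-n_c)*k this chain gives two lines that bound the admissible mixing:
#
#   mu1 < mu2 (N - n_c) / (n_c - n_f)      (the coarse level is well defined)
#   mu1 < 1 - mu2 n_c / (n_c - n_f)        (the fine level is well defined)
#
# evaluated at the extreme module sizes (largest coarse/smallest fine for the
# first line, smallest coarse/largest fine for the second). The two lines
# cross, and the admissible region closes as mu2 grows.

#' Benchmark-network specification
#'
#' @param n_nodes Number of nodes N.
#' @param k_mean Average degree.
#' @param k_max Maximum degree.
#' @param degree_exponent Power-law exponent of the degree distribution
#'   (negative; default -2).
#' @param coarse_range Length-2 vector: smallest and largest coarse module
#'   size.
#' @param fine_range Length-2 vector: smallest and largest fine module size.
#' @param size_exponent Power-law exponent of both module-size distributions
#'   (default -1).
#' @param mu1 Fraction of a node's links to other coarse modules.
#' @param mu2 Fraction of a node's links to other fine modules within its own
#'   coarse module.
#' @param seed Integer seed; the generated edge list is deterministic given
#'   the seed.
#' @return An object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_nodes = 10000L, k_mean = 20, k_max = 100L,
                           degree_exponent = -2,
                           coarse_range = c(400L, 4000L),
                           fine_range = c(10L, 100L),
                           size_exponent = -1,
                           mu1 = 0.1, mu2 = 0.2, seed = 1L) {
  if (mu1 < 0 || mu2 < 0 || mu1 + mu2 > 1)
    stop_validation("need mu1, mu2 >= 0 and mu1 + mu2 <= 1")
  if (length(coarse_range) != 2L || length(fine_range) != 2L ||
      coarse_range[1] > coarse_range[2] || fine_range[1] > fine_range[2])
    stop_validation("size ranges must be (min, max) with min <= max")
  if (fine_range[2] > coarse_range[2])
    stop_validation("fine module sizes must be nested within coarse sizes")
  if (n_nodes < coarse_range[2])
    stop_validation("n_nodes must be at least the largest coarse size")
  if (k_max <= k_mean)
    stop_validation("k_max must exceed k_mean")
  structure(list(n_nodes = as.integer(n_nodes), k_mean = k_mean,
                 k_max = as.integer(k_max),
                 degree_exponent = degree_exponent,
                 coarse_range = as.integer(coarse_range),
                 fine_range = as.integer(fine_range),
                 size_exponent = size_exponent,
                 mu1 = mu1, mu2 = mu2, seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Admissible coarse-mixing range for a well-defined three-level hierarchy
#'
#' Evaluates, at the spec's extreme module sizes, the two lines in the
#' mu2-mu1 plane delimiting where the planted three-level structure is
#' topologically well defined (link density within fine modules greater than
#' within coarse modules between fine modules, greater than between coarse
#' modules). A pair `(mu2, mu1)` is well defined iff
#' `lower < mu1 < upper`.
#'
#' @param spec A `benchmark_spec` (its own `mu1`, `mu2` are ignored here).
#' @param mu2 Fine-level mixing value(s) at which to evaluate the bounds.
#' @return A data frame with columns `mu2`, `lower`, `upper`, `line_coarse`
#'   (bound from the coarse-level condition), `line_fine` (bound from the
#'   fine-level condition). `upper` is the minimum of the two lines; `lower`
#'   is 0. The region is non-empty where `upper > 0` and closes where the
#'   fine-level line reaches zero.
#' @examples
#' sp <- benchmark_spec(n_nodes = 10000, coarse_range = c(400, 4000),
#'                      fine_range = c(10, 100))
#' feasible_mu1_bounds(sp, mu2 = c(0.1, 0.3, 0.8))
#' @export
feasible_mu1_bounds <- function(spec, mu2) {
  if (!inherits(spec, "benchmark_spec"))
    stop_validation("spec must be a benchmark_spec")
  nf_min <- spec$fine_range[1]; nf_max <- spec$fine_range[2]
  nc_min <- spec$coarse_range[1]; nc_max <- spec$coarse_range[2]
  N <- spec$n_nodes
  if (nf_max >= nc_min)
    stop_validation("degenerate sizes: largest fine module (%d) must be smaller than smallest coarse module (%d)",
                    nf_max, nc_min)
  line_coarse <- mu2 * (N - nc_max) / (nc_max - nf_min)
  line_fine <- 1 - mu2 * nc_min / (nc_min - nf_max)
  upper <- pmin(line_coarse, line_fine)
  data.frame(mu2 = mu2, lower = 0, upper = upper,
             line_coarse = line_coarse, line_fine = line_fine)
}

#' Is a mixing pair inside the well-defined region?
#' @inheritParams feasible_mu1_bounds
#' @param mu1 Coarse-level mixing value(s).
#' @return Logical vector.
#' @export
well_defined_hierarchy <- function(spec, mu1, mu2) {
  b <- feasible_mu1_bounds(spec, mu2)
  mu1 > b$lower & mu1 < b$upper
}

# ---- sampling helpers ------------------------------------------------------

# Inverse-CDF draw from a continuous power law x^alpha truncated to [a, b].
#' @keywords internal
#' @noRd
rpowerlaw <- function(n, a, b, alpha) {
  u <- stats::runif(n)
  if (abs(alpha + 1) < 1e-12) {
    exp(log(a) + u * (log(b) - log(a)))
  } else {
    e <- alpha + 1
    (u * (b^e - a^e) + a^e)^(1 / e)
  }
}

# Mean of the continuous truncated power law, used to calibrate the lower
# cutoff so that the realized average degree matches k_mean.
#' @keywords internal
#' @noRd
powerlaw_mean <- function(a, b, alpha) {
  if (abs(alpha + 1) < 1e-12) {
    (b - a) / (log(b) - log(a))
  } else if (abs(alpha + 2) < 1e-12) {
    log(b / a) / (1 / a - 1 / b)
  } else {
    e1 <- alpha + 1; e2 <- alpha + 2
    (e1 / e2) * (b^e2 - a^e2) / (b^e1 - a^e1)
  }
}

#' @keywords internal
#' @noRd
sample_degrees <- function(n, k_mean, k_max, alpha) {
  f <- function(a) powerlaw_mean(a, k_max, alpha) - k_mean
  if (f(1) > 0) {
    a <- 1
  } else {
    a <- stats::uniroot(f, c(1, k_max - 1e-6), tol = 1e-10)$root
  }
  k <- as.integer(round(rpowerlaw(n, a, k_max, alpha)))
  pmin(pmax(k, 1L), k_max)
}

# Tile `total` nodes with sizes from a truncated power law; the last size is
# clamped to the remainder when the remainder is admissible, otherwise the
# whole draw is retried.
#' @keywords internal
#' @noRd
sample_sizes <- function(total, range, alpha, max_tries = 500L) {
  for (try in seq_len(max_tries)) {
    sizes <- integer(0)
    rem <- total
    ok <- TRUE
    while (rem > 0L) {
      s <- as.integer(round(rpowerlaw(1, range[1], range[2], alpha)))
      s <- min(max(s, range[1]), range[2])
      if (s > rem) s <- rem
      if (s < range[1]) { ok <- FALSE; break }
      sizes <- c(sizes, s)
      rem <- rem - s
    }
    if (ok) return(sizes)
  }
  stop(sprintf("could not tile %d nodes with sizes in [%d, %d] after %d tries",
               total, range[1], range[2], max_tries), call. = FALSE)
}

# Split k stubs into pools with target fractions: floor the targets, then
# assign the remaining stubs at random with probability proportional to the
# fractional parts (unbiased, unlike a deterministic largest-remainder rule).
#' @keywords internal
#' @noRd
split_stubs <- function(k, fracs) {
  raw <- k * fracs
  base <- floor(raw)
  rem <- k - sum(base)
  if (rem > 0L) {
    frac <- raw - base
    pick <- which(frac > 0)
    if (length(pick) > 1L)
      pick <- sample(pick, rem, prob = frac[pick])
    base[pick] <- base[pick] + 1
  }
  as.integer(base)
}

# Random pairing of stubs with swap-rewiring until every edge satisfies
# `ok_pair` and is globally unique. Retries from a fresh shuffle a few times
# and errors when the rewiring budget runs out.
#' @keywords internal
#' @noRd
match_stubs <- function(stubs, ok_pair, edge_env, max_rounds = 2000L,
                        max_attempts = 3L) {
  if (length(stubs) == 0L) return(NULL)
  if (length(stubs) %% 2L != 0L)
    stop("internal error: odd number of stubs in pool", call. = FALSE)
  m <- length(stubs) / 2L
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  bad_edge <- function(a, b) {
    a == b | !ok_pair(a, b) |
      vapply(ekey(a, b), function(k) !is.null(edge_env[[k]]), logical(1))
  }
  dup_within <- function(a, b) {
    k <- ekey(a, b)
    duplicated(k) | duplicated(k, fromLast = TRUE)
  }
  for (attempt in seq_len(max_attempts)) {
    sh <- sample(stubs)
    u <- sh[seq_len(m)]
    v <- sh[m + seq_len(m)]
    for (round in seq_len(max_rounds)) {
      bad <- which(bad_edge(u, v) | dup_within(u, v))
      if (!length(bad)) {
        for (k in ekey(u, v)) edge_env[[k]] <- TRUE
        return(cbind(u, v))
      }
      partners <- sample.int(m, length(bad), replace = TRUE)
      for (i in seq_along(bad)) {
        b1 <- bad[i]; b2 <- partners[i]
        if (b1 == b2) next
        # swap the second endpoints of the two pairs
        tmp <- v[b1]; v[b1] <- v[b2]; v[b2] <- tmp
      }
    }
  }
  NULL  # caller falls back to the greedy matcher
}

# Greedy largest-first matching (Havel-Hakimi style): repeatedly wire the
# node with the most remaining stubs to the admissible partners with the most
# remaining stubs. Handles the dense small modules that random matching
# cannot realize; stubs that cannot be placed are returned for promotion to
# the next-coarser pool.
#' @keywords internal
#' @noRd
greedy_match <- function(counts, ok_partner, edge_env) {
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  rem <- counts
  edges_u <- integer(0); edges_v <- integer(0)
  leftover <- integer(length(counts))
  active <- which(rem > 0L)
  while (length(active) > 1L) {
    u <- active[which.max(rem[active])]
    partners <- active[active != u & ok_partner(u, active)]
    if (length(partners)) {
      keys <- ekey(u, partners)
      free <- vapply(keys, function(k) is.null(edge_env[[k]]), logical(1))
      partners <- partners[free]
    }
    if (!length(partners)) {
      leftover[u] <- leftover[u] + rem[u]
      rem[u] <- 0L
      active <- active[active != u]
      next
    }
    o <- order(rem[partners], stats::runif(length(partners)),
               decreasing = TRUE)
    take <- partners[o[seq_len(min(rem[u], length(partners)))]]
    for (p in take) edge_env[[ekey(u, p)]] <- TRUE
    edges_u <- c(edges_u, rep(u, length(take)))
    edges_v <- c(edges_v, take)
    leftover[u] <- leftover[u] + rem[u] - length(take)
    rem[u] <- 0L
    rem[take] <- rem[take] - 1L
    active <- which(rem > 0L)
  }
  if (length(active) == 1L) leftover[active] <- leftover[active] + rem[active]
  list(edges = cbind(edges_u, edges_v), leftover = leftover)
}

# Match one stub pool: random configuration-model pairing with rewiring
# first, greedy largest-first as fallback. `counts` has one entry per
# network node (0 outside the pool); returns edges plus per-node leftover
# stubs the pool could not place.
#' @keywords internal
#' @noRd
match_pool <- function(counts, ok_partner, edge_env) {
  total <- sum(counts)
  if (total == 0L)
    return(list(edges = cbind(integer(0), integer(0)),
                leftover = integer(length(counts))))
  leftover0 <- integer(length(counts))
  if (total %% 2L == 1L) {  # parity: set one stub of the largest node aside
    u <- which.max(counts)
    counts[u] <- counts[u] - 1L
    leftover0[u] <- 1L
  }
  nodes <- which(counts > 0L)
  stubs <- rep(nodes, counts[nodes])
  ok_pair <- function(a, b) ok_partner(a, b)
  res <- match_stubs(stubs, ok_pair, edge_env,
                     max_rounds = 200L, max_attempts = 2L)
  if (!is.null(res))
    return(list(edges = res, leftover = leftover0))
  g <- greedy_match(counts, ok_partner, edge_env)
  list(edges = g$edges, leftover = g$leftover + leftover0)
}

# ---- generator -------------------------------------------------------------

#' Generate a hierarchical benchmark network
#'
#' Builds a scale-free network with planted coarse and fine modules at the
#' spec's mixing parameters (which need not lie in the well-defined region;
#' generation outside it is how breakdown is studied). Node stubs are split
#' into within-fine, within-coarse and between-coarse pools and matched
#' within each pool; high-degree nodes are placed in modules large enough to
#' host their within-module stubs (largest-fit reassignment), and odd stub
#' pools are balanced by promoting single stubs to the next-coarser pool.
#'
#' @param spec A `benchmark_spec`.
#' @param seed Optional override of `spec$seed`.
#' @return A list: `network` (undirected unit-weight `flownet`), `coarse` and
#'   `fine` (integer membership vectors; `fine` refines `coarse`),
#'   `realized_mu1` and `realized_mu2` (realized link fractions), and `spec`.
#' @examples
#' sp <- benchmark_spec(n_nodes = 300, k_mean = 10, k_max = 30,
#'                      coarse_range = c(60, 150), fine_range = c(10, 30),
#'                      mu1 = 0.1, mu2 = 0.2, seed = 7)
#' bench <- generate_hierarchical_benchmark(sp)
#' @export
generate_hierarchical_benchmark <- function(spec, seed = NULL) {
  if (!inherits(spec, "benchmark_spec"))
    stop_validation("spec must be a benchmark_spec")
  set.seed(if (is.null(seed)) spec$seed else seed)
  N <- spec$n_nodes
  coarse_sizes <- sample_sizes(N, spec$coarse_range, spec$size_exponent)
  fine_sizes_by_coarse <- lapply(coarse_sizes, sample_sizes,
                                 range = spec$fine_range,
                                 alpha = spec$size_exponent)
  n_coarse <- length(coarse_sizes)
  fine_sizes <- unlist(fine_sizes_by_coarse)
  fine_coarse <- rep(seq_len(n_coarse), lengths(fine_sizes_by_coarse))
  n_fine <- length(fine_sizes)

  degrees <- sample_degrees(N, spec$k_mean, spec$k_max, spec$degree_exponent)
  fr <- c(1 - spec$mu1 - spec$mu2, spec$mu2, spec$mu1)
  pools <- t(vapply(degrees, split_stubs, integer(3), fracs = fr))
  kf <- pools[, 1]; kc <- pools[, 2]; kb <- pools[, 3]

  # place nodes in fine modules; nodes with many within-fine stubs need
  # modules large enough to host them (largest-fit when nothing else does)
  slots <- fine_sizes
  fine_of <- integer(N)
  for (u in order(kf, decreasing = TRUE)) {
    cand <- which(slots > 0L & fine_sizes - 1L >= kf[u])
    if (length(cand)) {
      pick <- if (length(cand) == 1L) cand else
        sample(cand, 1L, prob = slots[cand])
    } else {
      open <- which(slots > 0L)
      pick <- open[which.max(fine_sizes[open])]
      spare <- kf[u] - (fine_sizes[pick] - 1L)
      kf[u] <- fine_sizes[pick] - 1L    # clip; excess goes one pool coarser
      kc[u] <- kc[u] + spare
    }
    fine_of[u] <- pick
    slots[pick] <- slots[pick] - 1L
  }
  coarse_of <- fine_coarse[fine_of]

  # match stubs pool by pool (finest first); stubs a pool cannot place are
  # promoted to the next-coarser pool, stray between-coarse stubs are dropped
  edge_env <- new.env(parent = emptyenv(), size = 4L * N)
  edges <- vector("list", n_fine + n_coarse + 1L)
  i <- 0L
  for (fm in seq_len(n_fine)) {
    counts <- integer(N)
    mem <- which(fine_of == fm)
    counts[mem] <- kf[mem]
    i <- i + 1L
    r <- match_pool(counts, function(a, b) rep(TRUE, length(b)), edge_env)
    edges[[i]] <- r$edges
    # unplaced stubs move one pool coarser, but never into a pool whose
    # target fraction is zero (mu = 0 must mean no such links at all)
    if (spec$mu2 > 0) kc <- kc + r$leftover
    else if (spec$mu1 > 0) kb <- kb + r$leftover
  }
  for (cm in seq_len(n_coarse)) {
    counts <- integer(N)
    mem <- which(coarse_of == cm)
    counts[mem] <- kc[mem]
    i <- i + 1L
    r <- match_pool(counts, function(a, b) fine_of[a] != fine_of[b], edge_env)
    edges[[i]] <- r$edges
    if (spec$mu1 > 0) kb <- kb + r$leftover
  }
  i <- i + 1L
  r <- match_pool(kb, function(a, b) coarse_of[a] != coarse_of[b], edge_env)
  edges[[i]] <- r$edges
  el <- do.call(rbind, edges)
  colnames(el) <- NULL
  net <- flow_network(data.frame(from = el[, 1], to = el[, 2], weight = 1),
                      n_nodes = N, directed = FALSE)

  same_fine <- fine_of[el[, 1]] == fine_of[el[, 2]]
  same_coarse <- coarse_of[el[, 1]] == coarse_of[el[, 2]]
  m_tot <- nrow(el)
  list(network = net,
       coarse = coarse_of,
       fine = fine_of,
       realized_mu1 = sum(!same_coarse) / m_tot,
       realized_mu2 = sum(same_coarse & !same_fine) / m_tot,
       spec = spec)
}
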