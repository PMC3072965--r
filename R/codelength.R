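# The map equation.
#
# The description length of one step of the random walk, given a partition, is
# the sum over codebooks of (rate of codebook use) x (entropy of the codeword
# distribution in that codebook):
#
#   two-level:  L = q H(Q) + sum_i p_i H(P_i)
#
# where the index codebook Q holds the relative rates at which the modules are
# entered (q = total enter rate) and module codebook P_i holds the visit rates
# of the member nodes plus the module's own exit rate, used at total rate
# p_i = sum of member rates + exit_i.
#
# The hierarchical generalization nests index codebooks: the root codebook
# holds the enter rates of the coarsest modules; each intermediate module's
# subindex codebook holds the enter rates of its children plus its own exit
# rate; each finest module's codebook holds its member node rates plus its own
# exit rate. All entropies are in bits.

#' Two-level map equation
#'
#' Evaluates the classic (flat) map equation for a hard partition.
#'
#' @param flow A corrected `flowfield` (see [network_flow()]).
#' @param modules Integer module membership per node (any labels; coerced), or
#'   a depth-2 `hpartition`.
#' @return A `codelength_report`: `total_bits`, `index_bits`, `module_bits`,
#'   per-vertex terms, and level summaries.
#' @examples
#' fx <- triangle_hierarchy_network()
#' fl <- network_flow(fx$network)
#' two_level_codelength(fl, rep(1:9, each = 3))  # 3.57 bits
#' @export
two_level_codelength <- function(flow, modules) {
  if (!inherits(flow, "flowfield")) stop_validation("flow must be a flowfield")
  if (!isTRUE(flow$corrected))
    stop_validation("flow must be teleportation-corrected (see network_flow)")
  if (inherits(modules, "hpartition")) {
    if (n_levels(modules) != 2L)
      stop_validation("modules must be a flat (depth-2) partition")
    modules <- vapply(modules$paths, `[`, integer(1), 1L)
  }
  if (length(modules) != flow$n_nodes)
    stop_validation("membership covers %d nodes but the flow field has %d",
                    length(modules), flow$n_nodes)
  mem <- as.integer(factor(modules, levels = unique(modules)))
  m <- max(mem)
  p_node <- flow$node_rate
  p_mod <- as.numeric(rowsum(p_node, mem))
  l <- flow$links
  ma <- mem[l$from]; mb <- mem[l$to]
  crossing <- ma != mb
  exit <- numeric(m); enter <- numeric(m)
  if (any(crossing)) {
    ex <- rowsum(l$flow[crossing], ma[crossing])
    en <- rowsum(l$flow[crossing], mb[crossing])
    exit[as.integer(rownames(ex))] <- ex
    enter[as.integer(rownames(en))] <- en
  }
  index_bits <- codebook_bits(enter)
  mod_const <- as.numeric(rowsum(plogp(p_node), mem))
  module_bits <- plogp(exit + p_mod) - plogp(exit) - mod_const
  vertices <- data.frame(
    path = as.character(seq_len(m)), level = 1L,
    flow = p_mod, enter = enter, exit = exit,
    use_rate = exit + p_mod, bits = module_bits, finest = TRUE,
    stringsAsFactors = FALSE)
  new_codelength_report(
    total_bits = index_bits + sum(module_bits),
    index_bits = index_bits,
    module_bits = sum(module_bits),
    num_levels = 2L,
    num_modules = m,
    vertices = vertices)
}

#' Hierarchical map equation
#'
#' Evaluates the multilevel map equation for an arbitrary hierarchical
#' partition. On a depth-2 tree this reduces exactly to
#' [two_level_codelength()].
#'
#' @param flow A corrected `flowfield`.
#' @param partition An `hpartition`.
#' @return A `codelength_report`.
#' @examples
#' fx <- triangle_hierarchy_network()
#' fl <- network_flow(fx$network)
#' hierarchical_codelength(fl, fx$partition)  # 3.48 bits
#' @export
hierarchical_codelength <- function(flow, partition) {
  ann <- annotate_partition(flow, partition)
  v <- ann$vertices
  paths <- partition$paths
  depth <- ann$depth
  maxd <- max(depth)
  # children bookkeeping: internal children enter-rate sums and plogp sums
  parent_of <- function(path) sub(":[0-9]+$", "", path)
  child_enter_sum <- structure(numeric(nrow(v)), names = v$path)
  child_enter_plogp <- child_enter_sum
  deeper <- v$level > 1L
  par <- character(0)
  if (any(deeper)) {
    par <- parent_of(v$path[deeper])
    es <- rowsum(v$enter[deeper], par)
    ep <- rowsum(plogp(v$enter[deeper]), par)
    child_enter_sum[rownames(es)] <- es
    child_enter_plogp[rownames(ep)] <- ep
  }
  # direct leaf members: nodes whose finest module is this vertex
  finest_key <- vapply(paths, paste, character(1), collapse = ":")
  leaf_rate_sum <- structure(numeric(nrow(v)), names = v$path)
  leaf_plogp_sum <- leaf_rate_sum
  lr <- rowsum(flow$node_rate, finest_key)
  lp <- rowsum(plogp(flow$node_rate), finest_key)
  leaf_rate_sum[rownames(lr)] <- lr
  leaf_plogp_sum[rownames(lp)] <- lp
  # per-vertex codebook: {enter rates of children} u {direct member rates} u {own exit}
  use <- child_enter_sum + leaf_rate_sum + v$exit
  bits <- plogp(use) - child_enter_plogp - leaf_plogp_sum - plogp(v$exit)
  # root index codebook: enter rates of the top-level modules
  top <- v$level == 1L
  root_use <- sum(v$enter[top])
  root_bits <- plogp(root_use) - sum(plogp(v$enter[top]))
  vertices <- data.frame(
    path = v$path, level = v$level, flow = v$flow, enter = v$enter,
    exit = v$exit, use_rate = use, bits = bits,
    finest = !(v$path %in% par),
    stringsAsFactors = FALSE)
  new_codelength_report(
    total_bits = root_bits + sum(bits),
    index_bits = root_bits + sum(bits[!vertices$finest]),
    module_bits = sum(bits[vertices$finest]),
    num_levels = maxd + 1L,
    num_modules = as.integer(table(factor(v$level, levels = seq_len(maxd)))),
    vertices = vertices,
    root_bits = root_bits)
}

#' @keywords internal
#' @noRd
new_codelength_report <- function(total_bits, index_bits, module_bits,
                                  num_levels, num_modules, vertices,
                                  root_bits = index_bits) {
  structure(list(total_bits = total_bits, index_bits = index_bits,
                 module_bits = module_bits, num_levels = num_levels,
                 num_modules = num_modules, root_bits = root_bits,
                 vertices = vertices),
            class = "codelength_report")
}

#' @export
print.codelength_report <- function(x, ...) {
  cat(sprintf("Per-step description length: %.6f bits\n", x$total_bits))
  cat(sprintf("  index codebooks: %.6f bits; module codebooks: %.6f bits\n",
              x$index_bits, x$module_bits))
  cat(sprintf("  levels: %d; modules per level: %s\n", x$num_levels,
              paste(x$num_modules, collapse = ", ")))
  invisible(x)
}
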