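# Hierarchical partitions.
#
# A hierarchical partition is a rooted tree whose leaves are the network's
# nodes and whose internal vertices are modules, submodules, and so on. It is
# stored as one integer "module path" per node: the sequence of 1-based sibling
# indices from the top level down to the node's finest module. A flat
# (two-level) partition therefore has paths of length 1; the depth of a leaf in
# edges from the root is length(path) + 1.

#' Construct a hierarchical partition
#'
#' @param paths A list with one integer vector per node: the module path of
#'   that node from the coarsest level down to its finest module. All paths
#'   must have length at least 1 (nodes are never direct children of the
#'   root).
#' @param node_names Optional character labels, one per node.
#' @param canonical If `TRUE` (default), sibling indices are renumbered
#'   compactly in order of first appearance and redundant single-child chains
#'   are collapsed, so that no internal vertex has exactly one child that is
#'   itself a parent of further modules.
#' @return An object of class `hpartition`.
#' @examples
#' hp <- hpartition(list(c(1, 1), c(1, 1), c(1, 2), c(1, 2), c(2, 1), c(2, 1)))
#' n_levels(hp)
#' @export
hpartition <- function(paths, node_names = NULL, canonical = TRUE) {
  if (!is.list(paths) || length(paths) == 0L)
    stop_validation("paths must be a non-empty list of integer vectors")
  paths <- lapply(paths, function(p) {
    p <- as.integer(p)
    if (length(p) < 1L || anyNA(p) || any(p < 1L))
      stop_validation("each module path must be a vector of positive integers")
    p
  })
  if (canonical) paths <- canonicalize_paths(paths)
  if (!is.null(node_names)) {
    node_names <- as.character(node_names)
    if (length(node_names) != length(paths))
      stop_validation("node_names must have one entry per node")
  }
  structure(list(n_nodes = length(paths), paths = paths,
                 node_names = node_names),
            class = "hpartition")
}

# Collapse single-internal-child chains and renumber siblings by first
# appearance. The degenerate one-module partition (all paths equal and of
# length 1) is preserved: collapsing at the root never pushes leaves to
# depth 1.
#' @keywords internal
#' @noRd
canonicalize_paths <- function(paths) {
  rec <- function(plist, at_root) {
    len <- lengths(plist)
    if (all(len == 0L)) return(plist)
    tops <- vapply(plist, function(p) if (length(p)) p[1] else NA_integer_,
                   integer(1))
    has_leaf_children <- any(len == 0L)
    groups <- unique(tops[!is.na(tops)])
    if (!has_leaf_children && length(groups) == 1L &&
        (!at_root || all(len >= 2L))) {
      return(rec(lapply(plist, function(p) p[-1]), at_root))
    }
    out <- plist
    for (k in seq_along(groups)) {
      idx <- which(!is.na(tops) & tops == groups[k])
      sub <- rec(lapply(plist[idx], function(p) p[-1]), FALSE)
      out[idx] <- lapply(sub, function(p) c(k, p))
    }
    out
  }
  rec(paths, TRUE)
}

#' Flat membership vector to hierarchical partition
#'
#' @param membership Integer (or factor/character) module assignment per node.
#' @param node_names Optional node labels.
#' @return A depth-2 `hpartition` (root, modules, nodes).
#' @export
as_hpartition <- function(membership, node_names = NULL) {
  m <- as.integer(factor(membership, levels = unique(membership)))
  hpartition(lapply(m, function(x) x), node_names = node_names,
             canonical = FALSE)
}

#' Nested coarse/fine memberships to a three-level partition
#'
#' @param coarse Coarse module per node.
#' @param fine Fine module per node; must refine `coarse`.
#' @return A depth-3 `hpartition` when the fine level strictly refines the
#'   coarse one (collapsed otherwise).
#' @export
hp_nested <- function(coarse, fine) {
  coarse <- as.integer(factor(coarse, levels = unique(coarse)))
  fine <- as.integer(factor(fine, levels = unique(fine)))
  cf <- unique(data.frame(coarse, fine))
  if (anyDuplicated(cf$fine))
    stop_validation("fine partition does not refine the coarse partition")
  hpartition(mapply(function(a, b) c(a, b), coarse, fine, SIMPLIFY = FALSE))
}

#' @export
print.hpartition <- function(x, ...) {
  d <- lengths(x$paths) + 1L
  cat(sprintf("<hpartition> %d nodes, depth %s, %d top modules\n",
              x$n_nodes,
              if (min(d) == max(d)) max(d) else sprintf("%d-%d", min(d), max(d)),
              length(unique(vapply(x$paths, `[`, integer(1), 1L)))))
  invisible(x)
}

#' Number of levels of a hierarchical partition
#'
#' Counted as the maximum leaf depth in edges from the root; a flat partition
#' has 2 levels (root, modules, nodes).
#' @param partition An `hpartition`.
#' @return Integer.
#' @export
n_levels <- function(partition) {
  max(lengths(partition$paths)) + 1L
}

#' @keywords internal
#' @noRd
path_keys <- function(paths, level) {
  # key string of the level-`level` ancestor of each node, NA where the node's
  # finest module is above that level
  vapply(paths, function(p) {
    if (length(p) < level) NA_character_
    else paste(p[seq_len(level)], collapse = ":")
  }, character(1))
}

#' Top-level and finest-level flat slices of a hierarchical partition
#'
#' The top slice maps each node to its coarsest module; the finest slice maps
#' each node to its deepest containing module (each branch contributing its own
#' deepest level, which need not be the same across branches).
#'
#' @param partition An `hpartition`.
#' @return A list with integer vectors `top` and `finest`.
#' @export
level_slices <- function(partition) {
  top <- vapply(partition$paths, `[`, integer(1), 1L)
  fin <- vapply(partition$paths, paste, character(1), collapse = ":")
  list(top = as.integer(factor(top, levels = unique(top))),
       finest = as.integer(factor(fin, levels = unique(fin))))
}
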