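# Partition comparison and hierarchy summary statistics.

#' Normalized mutual information between two flat partitions
#'
#' Treats module labels as discrete random variables sampled by picking a
#' node uniformly at random; returns `2 I(X,Y) / (H(X) + H(Y))` with base-2
#' logarithms and the convention 0 log 0 = 0. The value is 1 for identical
#' partitions (including the degenerate pair where both place all nodes in
#' one module) and 0 for independent ones.
#'
#' @param partX,partY Module membership vectors (any label type) over the
#'   same nodes, in the same node order.
#' @return A number in `[0, 1]`.
#' @examples
#' normalized_mutual_information(c(1, 1, 2, 2), c(2, 2, 7, 7))  # 1
#' normalized_mutual_information(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 0
#' @export
normalized_mutual_information <- function(partX, partY) {
  if (length(partX) != length(partY))
    stop_validation("partitions cover different node sets (%d vs %d nodes)",
                    length(partX), length(partY))
  n <- length(partX)
  if (n == 0L) stop_validation("empty partitions")
  tab <- table(partX, partY)
  nx <- rowSums(tab); ny <- colSums(tab)
  hx <- entropy_bits(nx / n)
  hy <- entropy_bits(ny / n)
  if (hx + hy == 0) return(1)  # both trivial one-module partitions
  pxy <- tab / n
  px <- nx / n; py <- ny / n
  outer_p <- outer(px, py)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log2(pxy[nz] / outer_p[nz]))
  val <- 2 * mi / (hx + hy)
  min(max(val, 0), 1)
}

#' Summary statistics of a hierarchical partition
#'
#' The statistics used to summarize multilevel organization: the total number
#' of modules `M` across all levels, the number of modules holding more than
#' one percent of all nodes, the per-node average leaf depth (edges from the
#' root; exactly 2 for a flat partition), the per-node average size of the
#' finest containing module, and, when the two codelengths are supplied, the
#' compression gain of the multilevel over the two-level description.
#'
#' @param partition An `hpartition`.
#' @param flow Optional corrected `flowfield` (used only for node-count
#'   validation).
#' @param L_two_level,L_multi Optional codelengths (bits) of the best
#'   two-level and multilevel partitions.
#' @return A list: `n_modules`, `n_modules_over_1pct`, `mean_depth`,
#'   `mean_finest_module_size`, `compression_gain_pct` (NA when codelengths
#'   are not supplied).
#' @export
hierarchy_statistics <- function(partition, flow = NULL,
                                 L_two_level = NULL, L_multi = NULL) {
  if (!inherits(partition, "hpartition"))
    stop_validation("partition must be an hpartition")
  if (!is.null(flow) && flow$n_nodes != partition$n_nodes)
    stop_validation("partition and flow disagree on the node count")
  paths <- partition$paths
  n <- partition$n_nodes
  depth <- lengths(paths)
  prefixes <- unlist(lapply(paths, function(p)
    vapply(seq_along(p), function(k) paste(p[seq_len(k)], collapse = ":"),
           character(1))))
  counts <- table(prefixes)  # nodes under each module vertex, any level
  finest_key <- vapply(paths, paste, character(1), collapse = ":")
  finest_size <- table(finest_key)
  gain <- if (is.null(L_two_level) || is.null(L_multi)) NA_real_
          else max(0, 100 * (L_two_level - L_multi) / L_two_level)
  list(n_modules = length(counts),
       n_modules_over_1pct = sum(counts > 0.01 * n),
       mean_depth = mean(depth + 1),
       mean_finest_module_size = mean(as.numeric(finest_size[finest_key])),
       compression_gain_pct = gain)
}
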