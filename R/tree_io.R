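# Tree-file output: the de-facto community-detection format with one line per
# node, "module:path:leaf visit-rate \"name\"", siblings ordered by
# descending aggregate flow, plus a header recording the total codelength.

#' Write a hierarchical partition as a .tree file
#'
#' @param partition An `hpartition` over the flow field's nodes.
#' @param flow A corrected `flowfield`.
#' @param path Output file path.
#' @return Invisibly, the reordered `hpartition` actually written (sibling
#'   modules renumbered by descending aggregate flow).
#' @export
write_tree <- function(partition, flow, path) {
  ann <- annotate_partition(flow, partition)  # validates the node sets
  report <- hierarchical_codelength(flow, partition)
  v <- ann$vertices
  vflow <- structure(v$flow, names = v$path)
  # renumber sibling modules by descending aggregate flow
  remap <- new.env(parent = emptyenv())
  for (lvl in sort(unique(v$level))) {
    vs <- v[v$level == lvl, ]
    parent <- if (lvl == 1L) rep("", nrow(vs))
              else sub(":[0-9]+$", "", vs$path)
    for (par in unique(parent)) {
      sib <- vs[parent == par, ]
      new_idx <- rank(-sib$flow, ties.method = "first")
      for (i in seq_len(nrow(sib))) remap[[sib$path[i]]] <- new_idx[i]
    }
  }
  paths <- lapply(partition$paths, function(p) {
    vapply(seq_along(p), function(k)
      remap[[paste(p[seq_len(k)], collapse = ":")]], integer(1))
  })
  # order leaves within each finest module by descending visit rate
  finest <- vapply(paths, paste, character(1), collapse = ":")
  ord <- order(finest, -flow$node_rate, seq_along(paths))
  f_sorted <- finest[ord]
  leaf_idx <- stats::ave(seq_along(f_sorted), f_sorted, FUN = seq_along)
  nm <- flow$node_names
  if (is.null(nm)) nm <- as.character(seq_along(paths))
  lines <- sprintf("%s:%d %.10g \"%s\"",
                   f_sorted, leaf_idx, flow$node_rate[ord], nm[ord])
  header <- c(sprintf("# Codelength %.9f bits", report$total_bits),
              "# path flow name")
  writeLines(c(header, lines), path)
  invisible(hpartition(paths, node_names = partition$node_names,
                       canonical = FALSE))
}

#' Read a .tree file
#'
#' @param path Path to a file written by [write_tree()] (or any file whose
#'   lines are `path flow "name"` with colon-separated 1-based module paths
#'   whose last component indexes the leaf within its finest module).
#' @return A list: `partition` (an `hpartition`), `node_rate`, `node_names`,
#'   `node_order` (the node index encoded by each line's leaf position, when
#'   names are integers; otherwise line order) and `codelength` (bits, from
#'   the header; NA if absent).
#' @export
read_tree <- function(path) {
  raw <- readLines(path, warn = FALSE)
  header <- grep("^#", raw, value = TRUE)
  codelength <- NA_real_
  m <- regmatches(header, regexec("Codelength ([0-9.eE+-]+) bits", header))
  for (g in m) if (length(g) == 2L) codelength <- as.numeric(g[2])
  body <- raw[!grepl("^#", raw) & nzchar(trimws(raw))]
  if (!length(body)) stop_validation("tree file has no node lines: %s", path)
  parts <- regmatches(body,
                      regexec("^([0-9:]+) ([0-9.eE+-]+) \"(.*)\"\\s*$", body))
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop_validation("malformed tree line %d in %s", bad[1], path)
  pathstr <- vapply(parts, `[`, "", 2L)
  rate <- as.numeric(vapply(parts, `[`, "", 3L))
  name <- vapply(parts, `[`, "", 4L)
  split_paths <- lapply(strsplit(pathstr, ":", fixed = TRUE), as.integer)
  if (any(lengths(split_paths) < 2L))
    stop_validation("tree paths must have at least two components (module:leaf)")
  mod_paths <- lapply(split_paths, function(p) p[-length(p)])
  list(partition = hpartition(mod_paths, node_names = name),
       node_rate = rate, node_names = name, codelength = codelength)
}
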