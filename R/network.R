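# Network container and plain-text readers/writers.
#
# A network is the substrate of the random walk: n_nodes nodes joined by
# positively weighted links, optionally directed. Internally node ids are
# contiguous 1-based integers; input dialects (arbitrary edge-list labels,
# 1-based Pajek ids) are converted at the boundary and the original labels are
# retained in node_names.

#' Construct a network
#'
#' Builds the network object used throughout the package from a link table.
#' Duplicate links (same source and target, and for undirected networks the
#' same unordered pair) are aggregated by summing their weights. Self-loops are
#' kept; they are within-module steps for every partition.
#'
#' @param links A data frame or matrix with columns `from`, `to` and optionally
#'   `weight` (default 1). Node ids must be integers in `1..n_nodes`.
#' @param n_nodes Number of nodes. Defaults to the largest id in `links`.
#' @param directed Logical; if `FALSE` each link is stored once as an
#'   unordered pair.
#' @param node_names Optional character vector of node labels.
#' @return An object of class `flownet` with fields `n_nodes`, `directed`,
#'   `links` (data frame `from`, `to`, `weight`) and `node_names`.
#' @examples
#' net <- flow_network(data.frame(from = c(1, 2, 3), to = c(2, 3, 1)))
#' net$n_nodes
#' @export
flow_network <- function(links, n_nodes = NULL, directed = FALSE,
                         node_names = NULL) {
  links <- as.data.frame(links)
  if (nrow(links) == 0L) stop_validation("network has no links")
  if (ncol(links) == 2L) links$weight <- 1
  names(links)[1:3] <- c("from", "to", "weight")
  from <- as.integer(links$from)
  to <- as.integer(links$to)
  weight <- as.numeric(links$weight)
  if (anyNA(from) || anyNA(to) || anyNA(weight))
    stop_validation("links contain missing or non-numeric entries")
  if (any(weight <= 0))
    stop_validation("link weights must be positive")
  if (is.null(n_nodes)) n_nodes <- max(from, to)
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1L) stop_validation("network must have at least one node")
  if (any(from < 1L | from > n_nodes | to < 1L | to > n_nodes))
    stop_validation("link endpoint out of range 1..%d", n_nodes)
  if (!directed) {
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  }
  key <- (from - 1) * as.double(n_nodes) + to
  if (anyDuplicated(key)) {
    weight <- as.numeric(rowsum(weight, key, reorder = FALSE))
    keep <- !duplicated(key)
    from <- from[keep]; to <- to[keep]
  }
  if (!is.null(node_names)) {
    node_names <- as.character(node_names)
    if (length(node_names) != n_nodes)
      stop_validation("node_names must have length n_nodes")
  }
  structure(
    list(n_nodes = n_nodes, directed = isTRUE(directed),
         links = data.frame(from = from, to = to, weight = weight),
         node_names = node_names),
    class = "flownet"
  )
}

#' @export
print.flownet <- function(x, ...) {
  cat(sprintf("<flownet> %d nodes, %d %s links, total weight %g\n",
              x$n_nodes, nrow(x$links),
              if (x$directed) "directed" else "undirected",
              sum(x$links$weight)))
  invisible(x)
}

#' Node strengths (sum of incident link weights)
#'
#' For undirected networks self-loops count twice, following the usual
#' random-walk convention. For directed networks returns out-strength.
#' @param net A `flownet`.
#' @return Numeric vector of length `n_nodes`.
#' @export
node_strength <- function(net) {
  s <- numeric(net$n_nodes)
  l <- net$links
  if (net$directed) {
    add <- rowsum(l$weight, l$from)
    s[as.integer(rownames(add))] <- add
  } else {
    w <- c(l$weight, l$weight)
    idx <- c(l$from, l$to)  # self-loops appear twice, as intended
    add <- rowsum(w, idx)
    s[as.integer(rownames(add))] <- add
  }
  s
}

#' Read a whitespace-delimited edge list
#'
#' Lines have the form `src dst [weight]`; the weight defaults to 1. Node
#' labels may be arbitrary strings and are remapped to contiguous integer ids
#' in order of first appearance; the labels are kept in `node_names`.
#' Duplicate links are aggregated by summing weights. Lines that are empty or
#' start with `#` are skipped.
#'
#' @param path Path to the file.
#' @param directed Logical; interpret links as directed arcs.
#' @return A `flownet`.
#' @export
read_edge_list <- function(path, directed = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop_validation("empty edge-list file: %s", path)
  toks <- strsplit(trimws(lines), "\\s+")
  nt <- lengths(toks)
  bad <- which(nt < 2L | nt > 3L)
  if (length(bad))
    stop_validation("malformed edge-list line %d in %s", lineno[bad[1]], path)
  src <- vapply(toks, `[`, "", 1L)
  dst <- vapply(toks, `[`, "", 2L)
  w <- rep(1, length(toks))
  has_w <- nt == 3L
  if (any(has_w)) {
    wtxt <- vapply(toks[has_w], `[`, "", 3L)
    wnum <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(wnum))
      stop_validation("malformed weight on line %d in %s",
                      lineno[which(has_w)[which(is.na(wnum))[1]]], path)
    w[has_w] <- wnum
  }
  if (any(w <= 0))
    stop_validation("non-positive weight on line %d in %s",
                    lineno[which(w <= 0)[1]], path)
  labels <- unique(c(rbind(src, dst)))  # first-appearance order within lines
  ids_from <- match(src, labels)
  ids_to <- match(dst, labels)
  flow_network(data.frame(from = ids_from, to = ids_to, weight = w),
               n_nodes = length(labels), directed = directed,
               node_names = labels)
}

#' Write a network as a whitespace-delimited edge list
#' @param net A `flownet`.
#' @param path Output path.
#' @param use_names Write node labels instead of integer ids when available.
#' @export
write_edge_list <- function(net, path, use_names = !is.null(net$node_names)) {
  l <- net$links
  if (use_names && !is.null(net$node_names)) {
    a <- net$node_names[l$from]; b <- net$node_names[l$to]
  } else {
    a <- l$from; b <- l$to
  }
  writeLines(sprintf("%s %s %s", a, b, format(l$weight, digits = 15)), path)
  invisible(NULL)
}

#' Read a Pajek .net file
#'
#' Supports a `*Vertices N` section with optional quoted names followed by a
#' `*Edges` (undirected) or `*Arcs` (directed) section. Pajek's 1-based vertex
#' ids map directly onto the internal ids.
#'
#' @param path Path to the `.net` file.
#' @return A `flownet`; directed when the file declares `*Arcs`.
#' @export
read_pajek <- function(path) {
  raw <- readLines(path, warn = FALSE)
  if (!any(grepl("^\\*[Vv]ertices", raw)))
    stop_validation("missing *Vertices section in %s", path)
  if (!any(grepl("^\\*([Ee]dges|[Aa]rcs)", raw)))
    stop_validation("missing *Edges/*Arcs section in %s", path)
  g <- igraph::read_graph(path, format = "pajek")
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0L) stop_validation("Pajek file has no links: %s", path)
  w <- if ("weight" %in% igraph::edge_attr_names(g))
    igraph::E(g)$weight else rep(1, nrow(el))
  nm <- NULL
  for (attr in c("id", "name")) {
    if (attr %in% igraph::vertex_attr_names(g)) {
      nm <- as.character(igraph::vertex_attr(g, attr)); break
    }
  }
  flow_network(data.frame(from = el[, 1], to = el[, 2], weight = w),
               n_nodes = n, directed = igraph::is_directed(g),
               node_names = nm)
}

#' Write a network as a Pajek .net file
#' @param net A `flownet`.
#' @param path Output path.
#' @export
write_pajek <- function(net, path) {
  nm <- net$node_names
  if (is.null(nm)) nm <- as.character(seq_len(net$n_nodes))
  vert <- sprintf("%d \"%s\"", seq_len(net$n_nodes), nm)
  sect <- if (net$directed) "*Arcs" else "*Edges"
  l <- net$links
  lines <- c(sprintf("*Vertices %d", net$n_nodes), vert, sect,
             sprintf("%d %d %s", l$from, l$to, format(l$weight, digits = 15)))
  writeLines(lines, path)
  invisible(NULL)
}

#' Convert a network to an igraph graph
#' @param net A `flownet`.
#' @return An igraph graph with edge weights and optional vertex names.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(net$n_nodes, directed = net$directed)
  g <- igraph::add_edges(g, t(as.matrix(net$links[, c("from", "to")])))
  igraph::E(g)$weight <- net$links$weight
  if (!is.null(net$node_names)) igraph::V(g)$name <- net$node_names
  g
}
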