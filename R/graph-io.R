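#' Read a network from a plain-text edge list
#'
#' Reads whitespace-delimited edge lists in the dialects used by the KONECT
#' and SNAP repositories. Lines starting with \code{#} or \code{%} are
#' treated as comments; the first two tokens on each remaining line are the
#' endpoint labels and any further tokens (weights, timestamps) are ignored.
#' Self-loops are dropped and duplicate or reversed-duplicate edges are
#' collapsed, so the result is always a simple undirected graph. Node order
#' is first-appearance order in the file, which fixes the row/column order
#' of every matrix derived from the graph.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple \code{igraph} with character vertex names.
#' @examples
#' f <- tempfile()
#' writeLines(c("% a comment", "0 1", "1 2 5.0"), f)
#' g <- read_edgelist(f)
#' igraph::vcount(g) # 3
#' @export
read_edgelist <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read edge list: file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*([#%]|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    stop("edge list contains no data lines: ", path)
  }
  tokens <- strsplit(trimws(lines), "\\s+")
  ntok <- lengths(tokens)
  if (any(ntok < 2L)) {
    bad <- lineno[which(ntok < 2L)[1L]]
    stop("parse error at line ", bad, ": expected at least 2 tokens")
  }
  u <- vapply(tokens, `[[`, character(1), 1L)
  v <- vapply(tokens, `[[`, character(1), 2L)
  graph_from_pairs(u, v)
}

#' Read a network from a GML file
#'
#' Thin wrapper over \code{igraph}'s GML reader that coerces the result to a
#' simple undirected graph with character vertex names.
#'
#' @param path Path to the GML file.
#' @return An undirected simple \code{igraph}.
#' @export
read_gml <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read GML: file not found: ", path)
  }
  g <- igraph::read_graph(path, format = "gml")
  g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  } else {
    igraph::V(g)$name <- as.character(igraph::V(g)$name)
  }
  g
}

# Build a simple undirected graph from parallel endpoint label vectors,
# preserving first-appearance node order.
graph_from_pairs <- function(u, v) {
  labels <- unique(c(rbind(u, v)))
  keep <- u != v
  u <- u[keep]
  v <- v[keep]
  iu <- match(u, labels)
  iv <- match(v, labels)
  lo <- pmin(iu, iv)
  hi <- pmax(iu, iv)
  dup <- duplicated(lo * (length(labels) + 1) + hi)
  el <- cbind(lo[!dup], hi[!dup])
  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  igraph::V(g)$name <- labels
  g
}

#' Write a network as a canonical edge list
#'
#' Writes one edge per line ("u v"), endpoints ordered within each line by
#' vertex index and lines sorted, newline-terminated. The output round-trips
#' through \code{\link{read_edgelist}}.
#'
#' @param graph An \code{igraph}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_edgelist <- function(graph, path) {
  stopifnot(igraph::is_igraph(graph))
  el <- igraph::as_edgelist(graph, names = TRUE)
  if (nrow(el) > 0) {
    idx <- match(el, node_labels(graph))
    dim(idx) <- dim(el)
    swap <- idx[, 1] > idx[, 2]
    el[swap, ] <- el[swap, c(2, 1)]
    idx[swap, ] <- idx[swap, c(2, 1)]
    el <- el[order(idx[, 1], idx[, 2]), , drop = FALSE]
  }
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

# Vertex labels as characters; unnamed graphs get their 1-based indices.
node_labels <- function(graph) {
  nm <- igraph::V(graph)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(graph))) else as.character(nm)
}

assert_simple_graph <- function(graph) {
  if (!igraph::is_igraph(graph)) {
    stop("expected an igraph object")
  }
  if (igraph::is_directed(graph)) {
    stop("expected an undirected graph")
  }
  if (igraph::any_loop(graph) || igraph::any_multiple(graph)) {
    stop("expected a simple graph (no self-loops or multi-edges)")
  }
  invisible(graph)
}
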