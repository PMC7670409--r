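#' Largest connected component
#'
#' Induced subgraph on the largest connected component, the standard
#' preprocessing step for disconnected source networks. Ties in component
#' size are broken deterministically in favour of the component containing
#' the smallest node index; original node labels are preserved.
#'
#' @param graph An undirected simple \code{igraph} with at least one node.
#' @return The induced \code{igraph} subgraph.
#' @export
largest_component <- function(graph) {
  assert_simple_graph(graph)
  if (igraph::vcount(graph) == 0L) {
    stop("largest component of an empty graph is undefined")
  }
  comp <- igraph::components(graph)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    first_member <- vapply(best, function(b) min(which(comp$membership == b)), integer(1))
    best <- best[which.min(first_member)]
  }
  igraph::induced_subgraph(graph, which(comp$membership == best))
}

#' Topology statistics of a network
#'
#' The summary statistics conventionally reported for link-prediction
#' benchmark networks: node and edge counts, average local clustering
#' coefficient C (averaged over nodes of degree >= 2), mean degree <k>,
#' mean shortest-path length <d> (unweighted hops, averaged over unordered
#' reachable pairs within the largest connected component), density rho, and
#' degree heterogeneity H = <k^2>/<k>^2. The un-normalised ratio <k^2>/<k>
#' is also reported as \code{heterogeneity_alt} since both conventions
#' circulate in the literature.
#'
#' @param graph An undirected simple \code{igraph} with at least 2 nodes.
#' @return An object of class \code{topology_stats}: a list with fields
#'   \code{n_nodes}, \code{n_edges}, \code{clustering}, \code{mean_degree},
#'   \code{mean_path_length}, \code{density}, \code{heterogeneity},
#'   \code{heterogeneity_alt}.
#' @examples
#' g <- canonical_graph("complete", 5)
#' topology_stats(g)$clustering # 1
#' @export
topology_stats <- function(graph) {
  assert_simple_graph(graph)
  n <- igraph::vcount(graph)
  if (n < 2L) {
    stop("topology statistics require at least 2 nodes")
  }
  m <- igraph::ecount(graph)
  k <- igraph::degree(graph)
  local_c <- igraph::transitivity(graph, type = "local", isolates = "NaN")
  eligible <- is.finite(local_c) & k >= 2
  clustering <- if (any(eligible)) mean(local_c[eligible]) else 0
  lcc <- largest_component(graph)
  d <- igraph::distances(lcc)
  du <- d[upper.tri(d)]
  mean_path <- if (length(du) > 0) mean(du[is.finite(du)]) else NA_real_
  mk <- mean(k)
  mk2 <- mean(k^2)
  structure(list(
    n_nodes = n,
    n_edges = m,
    clustering = clustering,
    mean_degree = mk,
    mean_path_length = mean_path,
    density = 2 * m / (n * (n - 1)),
    heterogeneity = if (mk > 0) mk2 / mk^2 else NA_real_,
    heterogeneity_alt = if (mk > 0) mk2 / mk else NA_real_
  ), class = "topology_stats")
}

#' @export
print.topology_stats <- function(x, ...) {
  cat(sprintf(
    paste0("Network topology: %d nodes, %d edges\n",
           "  clustering C = %.3f   mean degree <k> = %.3f\n",
           "  mean path length <d> = %.3f   density rho = %.3f\n",
           "  heterogeneity <k^2>/<k>^2 = %.3f   (<k^2>/<k> = %.3f)\n"),
    x$n_nodes, x$n_edges, x$clustering, x$mean_degree,
    x$mean_path_length, x$density, x$heterogeneity, x$heterogeneity_alt
  ))
  invisible(x)
}

#' Statistics derivable from node and edge counts alone
#'
#' Mean degree 2|E|/|V| and density 2|E|/(|V|(|V|-1)). Useful for checking
#' published network summary tables against their printed counts.
#'
#' @param n_nodes,n_edges Node and edge counts (vectorised).
#' @return A data frame with columns \code{n_nodes}, \code{n_edges},
#'   \code{mean_degree}, \code{density}.
#' @export
count_stats <- function(n_nodes, n_edges) {
  stopifnot(length(n_nodes) == length(n_edges), all(n_nodes >= 2))
  data.frame(
    n_nodes = n_nodes,
    n_edges = n_edges,
    mean_degree = 2 * n_edges / n_nodes,
    density = 2 * n_edges / (n_nodes * (n_nodes - 1))
  )
}
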