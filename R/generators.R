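#' Seeded Erdos-Renyi random graph
#'
#' G(n, p): each of the n(n-1)/2 unordered node pairs is included as an
#' edge independently with probability p. Deterministic for a fixed seed
#' (R's Mersenne-Twister stream).
#'
#' @param n Number of nodes (>= 2).
#' @param p Edge probability in [0, 1].
#' @param seed Integer RNG seed.
#' @return An undirected simple \code{igraph} with nodes labelled
#'   \code{"1"..."n"}.
#' @export
erdos_renyi_graph <- function(n, p, seed) {
  if (!is.numeric(n) || n < 2) stop("n must be at least 2")
  if (!is.numeric(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  n <- as.integer(n)
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(pairs[keep, , drop = FALSE]))
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Seeded stochastic block model graph
#'
#' Planted-community random graph: node pairs within a block are linked
#' with probability \code{p_in}, pairs across blocks with \code{p_out}.
#' With p_in > p_out the graph carries community structure, the regime in
#' which similarity-based link prediction beats chance. With
#' p_in = p_out = p the model reduces to Erdos-Renyi G(n, p).
#'
#' @param block_sizes Integer vector (length >= 2) of block sizes.
#' @param p_in,p_out Within- and between-block edge probabilities.
#' @param seed Integer RNG seed.
#' @return An undirected simple \code{igraph}; vertex attribute
#'   \code{block} records block membership.
#' @export
sbm_graph <- function(block_sizes, p_in, p_out, seed) {
  if (length(block_sizes) < 2 || any(block_sizes < 1)) {
    stop("need at least 2 blocks of size >= 1")
  }
  for (p in c(p_in, p_out)) {
    if (!is.numeric(p) || p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  n <- sum(block_sizes)
  membership <- rep(seq_along(block_sizes), block_sizes)
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p_pair <- ifelse(membership[pairs[, 1]] == membership[pairs[, 2]], p_in, p_out)
  keep <- runif(nrow(pairs)) < p_pair
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(pairs[keep, , drop = FALSE]))
  igraph::V(g)$name <- as.character(seq_len(n))
  igraph::V(g)$block <- membership
  g
}

#' Canonical deterministic graphs
#'
#' Standard small constructions used as worked-example substrates: the
#' path graph P_n, cycle C_n, star S_n (node 1 is the hub, n-1 leaves) and
#' complete graph K_n.
#'
#' @param name One of \code{"path"}, \code{"cycle"}, \code{"star"},
#'   \code{"complete"}.
#' @param n Number of nodes (path/star/complete n >= 2, cycle n >= 3).
#' @return An undirected simple \code{igraph} with nodes labelled
#'   \code{"1"..."n"}.
#' @examples
#' canonical_graph("path", 3) # the a-b-c worked-example graph
#' @export
canonical_graph <- function(name = c("path", "cycle", "star", "complete"), n) {
  name <- match.arg(name)
  n <- as.integer(n)
  min_n <- if (name == "cycle") 3L else 2L
  if (is.na(n) || n < min_n) {
    stop(sprintf("a %s graph requires n >= %d", name, min_n))
  }
  g <- switch(name,
    path = igraph::make_ring(n, circular = FALSE),
    cycle = igraph::make_ring(n, circular = TRUE),
    star = igraph::make_star(n, mode = "undirected", center = 1),
    complete = igraph::make_full_graph(n)
  )
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}
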