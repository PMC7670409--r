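#' Adjacency matrix of a simple graph
#'
#' Returns the symmetric 0/1 adjacency matrix A in node-index order with a
#' zero diagonal. The (u,v) entry of the k-th power of A counts walks of
#' length k between u and v, which is the quantity every walk-based
#' similarity index in this package sums.
#'
#' @param graph An undirected simple \code{igraph} with at least one node.
#' @param sparse Return a \code{Matrix} sparse matrix (default) or a dense
#'   base matrix.
#' @return A \code{|V| x |V|} symmetric 0/1 matrix with dimnames set to the
#'   node labels.
#' @export
adjacency_matrix <- function(graph, sparse = TRUE) {
  assert_simple_graph(graph)
  if (igraph::vcount(graph) == 0L) {
    stop("adjacency matrix of an empty graph is undefined")
  }
  a <- igraph::as_adjacency_matrix(graph, type = "both", sparse = TRUE)
  dimnames(a) <- list(node_labels(graph), node_labels(graph))
  if (sparse) a else as.matrix(a)
}

#' Degree-matrix diagonals and their guarded inverses
#'
#' The per-index degree weightings used throughout the package are diagonal
#' matrices; this helper returns their diagonal as a vector. All variants
#' are finite for every node, including isolated nodes (degree 0), which can
#' arise in training graphs after edge splitting:
#' \describe{
#'   \item{\code{degree}}{k}
#'   \item{\code{inverse}}{1/k for k > 0, else 0 (pseudo-inverse of D)}
#'   \item{\code{log-inverse}}{1/log(k) for k >= 2, else 0 (Adamic-Adar
#'     weighting; natural logarithm)}
#'   \item{\code{inv-sqrt}}{1/sqrt(k) for k > 0, else 0 (Salton weighting)}
#' }
#'
#' @param graph An undirected simple \code{igraph}.
#' @param variant One of \code{"degree"}, \code{"inverse"},
#'   \code{"log-inverse"}, \code{"inv-sqrt"}.
#' @return Numeric vector of diagonal entries, in node-index order.
#' @export
degree_weights <- function(graph,
                           variant = c("degree", "inverse", "log-inverse", "inv-sqrt")) {
  variant <- match.arg(variant)
  k <- unname(igraph::degree(graph))
  switch(variant,
    "degree" = as.numeric(k),
    "inverse" = ifelse(k > 0, 1 / k, 0),
    "log-inverse" = ifelse(k >= 2, 1 / log(k), 0),
    "inv-sqrt" = ifelse(k > 0, 1 / sqrt(k), 0)
  )
}

#' Walk propagator matrix of a similarity index
#'
#' Each index weights walks through its own propagator W: the plain
#' adjacency matrix A for the common-neighbour family (CN, SO, SA, LHN, HP,
#' HD), the degree-normalised D^-1 A for resource allocation, and
#' (log D)^-1 A for Adamic-Adar. The global extension of an index is a
#' resolvent in its propagator, so convergence of the walk series is
#' governed by beta * rho(W) < 1, with rho the spectral radius.
#'
#' @param graph An undirected simple \code{igraph}.
#' @param index Index name (see \code{\link{index_names}}); any of the
#'   CN-family names yields W = A.
#' @return A dense numeric matrix W.
#' @export
propagator_matrix <- function(graph, index = "CN") {
  index <- match_index(index)
  a <- adjacency_matrix(graph, sparse = FALSE)
  switch(index,
    RA = degree_weights(graph, "inverse") * a,
    AA = degree_weights(graph, "log-inverse") * a,
    a
  )
}

#' Spectral radius of a square matrix
#'
#' Magnitude of the dominant eigenvalue, used to check convergence of the
#' damped walk series (beta * rho(W) < 1). Small matrices use a full
#' eigendecomposition; larger ones a two-step power iteration on the
#' non-negative propagator, which handles the sign oscillation of bipartite
#' adjacency spectra.
#'
#' @param m A square numeric matrix (dense or \code{Matrix}).
#' @param tol Convergence tolerance for the iterative estimate.
#' @return Non-negative scalar estimate of the spectral radius.
#' @export
spectral_radius <- function(m, tol = 1e-8) {
  if (length(dim(m)) != 2L || nrow(m) != ncol(m)) {
    stop("spectral_radius requires a square matrix")
  }
  n <- nrow(m)
  if (n == 0L) {
    stop("spectral radius of an empty matrix is undefined")
  }
  if (n <= 800L) {
    ev <- eigen(as.matrix(m), only.values = TRUE)$values
    return(max(Mod(ev)))
  }
  x <- rep(1 / sqrt(n), n)
  est <- 0
  for (i in seq_len(500L)) {
    y <- as.numeric(m %*% x)
    z <- as.numeric(m %*% y)
    nz <- sqrt(sum(z^2))
    if (nz == 0) return(0)
    new_est <- sqrt(nz / sqrt(sum(x^2)))
    x <- z / nz
    if (abs(new_est - est) < tol * max(1, new_est)) {
      return(new_est)
    }
    est <- new_est
  }
  est
}
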