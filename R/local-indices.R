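#' Local similarity scores, vectorised
#'
#' Computes a full matrix of local similarity scores from walk counts and
#' degrees. Writing d_u for the degree of u and CN(u,v) for the number of
#' common neighbours (the (u,v) entry of A^2), the indices are:
#' \describe{
#'   \item{CN}{common neighbours, A^2}
#'   \item{RA}{resource allocation, sum over common neighbours w of 1/d_w,
#'     i.e. A D^-1 A}
#'   \item{AA}{Adamic-Adar, sum of 1/log(d_w), i.e. A (log D)^-1 A}
#'   \item{SO}{Sorensen, 2 CN / (d_u + d_v)}
#'   \item{SA}{Salton (cosine), CN / sqrt(d_u d_v)}
#'   \item{LHN}{Leicht-Holme-Newman, CN / (d_u d_v)}
#'   \item{HP}{hub promoted, CN / min(d_u, d_v)}
#'   \item{HD}{hub depressed, CN / max(d_u, d_v)}
#'   \item{PA}{preferential attachment, d_u d_v}
#'   \item{JACCARD}{CN / |Gamma(u) union Gamma(v)|}
#' }
#' Pairs with no common neighbours score 0 in all degree-normalised indices
#' (the 0/0 convention), so every entry is finite even in the presence of
#' isolated nodes. The logarithm in AA is natural, and common neighbours of
#' degree <= 1 contribute 0 to it (such nodes cannot be common neighbours in
#' an intact simple graph but can appear in matrix form after edge splits).
#'
#' @param graph An undirected simple \code{igraph}.
#' @param index Index name, one of \code{index_names()} (case-insensitive).
#' @return A \code{link_scores} matrix (symmetric, non-negative, zero
#'   diagonal) with attributes \code{index} and \code{family = "local"}.
#' @examples
#' g <- canonical_graph("star", 4) # hub of degree 3
#' local_scores(g, "RA")[2, 3]    # 1/3: one common neighbour of degree 3
#' @export
local_scores <- function(graph, index) {
  index <- match_index(index)
  assert_simple_graph(graph)
  a <- adjacency_matrix(graph, sparse = FALSE)
  k <- degree_weights(graph, "degree")
  s <- switch(index,
    CN = a %*% a,
    RA = a %*% (degree_weights(graph, "inverse") * a),
    AA = a %*% (degree_weights(graph, "log-inverse") * a),
    PA = outer(k, k),
    {
      cn <- a %*% a
      denom <- switch(index,
        SO = outer(k, k, `+`) / 2,
        SA = sqrt(outer(k, k)),
        LHN = outer(k, k),
        HP = outer(k, k, pmin),
        HD = outer(k, k, pmax),
        JACCARD = outer(k, k, `+`) - cn
      )
      safe_divide(cn, denom)
    }
  )
  new_link_scores(s, index, "local")
}

# Element-wise x/y with the 0/0 -> 0 convention used throughout: entries
# with zero numerator score 0 regardless of the denominator.
safe_divide <- function(x, y) {
  out <- array(0, dim = dim(x))
  nz <- x != 0
  out[nz] <- x[nz] / y[nz]
  out
}

#' Pairwise set-form similarity score (brute force)
#'
#' Literal evaluation of a local index from neighbour sets, used as an
#' independent oracle for the vectorised matrix forms. Deliberately naive:
#' it intersects neighbour sets per call and shares no code with
#' \code{\link{local_scores}}.
#'
#' @param graph An undirected simple \code{igraph}.
#' @param u,v Distinct node labels (or indices for unnamed graphs).
#' @param index Index name.
#' @return A single non-negative score.
#' @export
pairwise_score <- function(graph, u, v, index) {
  index <- match_index(index)
  labs <- node_labels(graph)
  iu <- match(as.character(u), labs)
  iv <- match(as.character(v), labs)
  if (is.na(iu) || is.na(iv)) {
    stop("unknown node label")
  }
  if (iu == iv) {
    stop("pairwise scores are defined for distinct nodes only")
  }
  nu <- as.integer(igraph::neighbors(graph, iu))
  nv <- as.integer(igraph::neighbors(graph, iv))
  common <- intersect(nu, nv)
  du <- length(nu)
  dv <- length(nv)
  cn <- length(common)
  deg <- function(w) length(igraph::neighbors(graph, w))
  switch(index,
    CN = cn,
    RA = if (cn == 0) 0 else sum(vapply(common, function(w) 1 / deg(w), numeric(1))),
    AA = if (cn == 0) 0 else sum(vapply(common, function(w) {
      dw <- deg(w)
      if (dw >= 2) 1 / log(dw) else 0
    }, numeric(1))),
    SO = if (cn == 0) 0 else 2 * cn / (du + dv),
    SA = if (cn == 0) 0 else cn / sqrt(du * dv),
    LHN = if (cn == 0) 0 else cn / (du * dv),
    HP = if (cn == 0) 0 else cn / min(du, dv),
    HD = if (cn == 0) 0 else cn / max(du, dv),
    PA = du * dv,
    JACCARD = if (cn == 0) 0 else cn / length(union(nu, nv))
  )
}
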