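#' Extension parameters for walk-series indices
#'
#' Bundles the knobs shared by all quasi-local and global indices: the
#' damping weight beta applied per unit walk length, the fallback truncation
#' order, and the policy applied when the infinite series diverges
#' (beta * rho(W) >= 1): either stop with an error or fall back to the
#' truncated partial sum (the default, with a warning).
#'
#' @param beta Damping weight in (0, 1); walks of length l are weighted
#'   beta^l, so small values concentrate on short walks. Default 0.001.
#' @param truncation_order Maximum walk length (>= 2) for truncated series.
#' @param convergence_policy \code{"truncate"} or \code{"error"}.
#' @return A list of class \code{extension_params}.
#' @export
extension_params <- function(beta = 0.001, truncation_order = 10L,
                             convergence_policy = c("truncate", "error")) {
  convergence_policy <- match.arg(convergence_policy)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1) {
    stop("beta must be a single number in (0, 1)")
  }
  truncation_order <- as.integer(truncation_order)
  if (is.na(truncation_order) || truncation_order < 2L) {
    stop("truncation_order must be an integer >= 2")
  }
  structure(list(beta = beta, truncation_order = truncation_order,
                 convergence_policy = convergence_policy),
            class = "extension_params")
}

as_extension_params <- function(params) {
  if (inherits(params, "extension_params")) params else do.call(extension_params, params)
}

# Resolvent series sum_{k>=1} beta^k W^k = (I - beta W)^-1 - I, evaluated by
# a linear solve against identity columns rather than an explicit inverse.
resolvent_series <- function(w, beta) {
  n <- nrow(w)
  solve(diag(n) - beta * w, diag(n)) - diag(n)
}

# Partial sum sum_{k=1}^{L} beta^k W^k by Horner recursion.
partial_series <- function(w, beta, L) {
  acc <- beta * w
  term <- acc
  if (L >= 2) {
    for (k in 2:L) {
      term <- beta * (term %*% w)
      acc <- acc + term
    }
  }
  acc
}

#' Katz similarity scores
#'
#' The Katz index sums all walks between two nodes, exponentially damped by
#' length: S(u,v) = sum_l beta^l (A^l)_{uv}, with closed form
#' (I - beta A)^-1 - I. It converges iff beta * rho(A) < 1; otherwise the
#' convergence policy applies. Katz is also the global extension of the
#' common-neighbour index (see \code{\link{global_scores}}).
#'
#' @param graph An undirected simple \code{igraph}.
#' @param beta Damping weight in (0, 1).
#' @param params Alternatively, an \code{\link{extension_params}} object
#'   (overrides \code{beta}).
#' @return A \code{link_scores} matrix.
#' @examples
#' g <- canonical_graph("path", 3)
#' katz_scores(g, beta = 0.1)[1, 3] # 0.01/0.98
#' @export
katz_scores <- function(graph, beta = 0.001, params = NULL) {
  if (is.null(params)) params <- extension_params(beta = beta)
  global_scores(graph, "CN", params = params)
}

#' Local-path similarity scores
#'
#' The local-path (LP) index A^2 + beta A^3: common neighbours plus a
#' damped count of length-3 walks. It is the quasi-local extension of the
#' common-neighbour index.
#'
#' @inheritParams katz_scores
#' @return A \code{link_scores} matrix.
#' @export
lp_scores <- function(graph, beta = 0.001, params = NULL) {
  if (is.null(params)) params <- extension_params(beta = beta)
  quasi_local_scores(graph, "CN", params = params)
}

#' Global walk-series similarity scores
#'
#' Extends a local index to the whole network by summing its damped walk
#' series. With K = (I - beta A)^-1 - I the Katz matrix:
#' \describe{
#'   \item{CN}{K itself (the Katz index)}
#'   \item{RA}{A (I - beta D^-1 A)^-1 - A: every walk is weighted by the
#'     inverse degrees of its interior nodes}
#'   \item{AA}{A (I - beta (log D)^-1 A)^-1 - A: interior nodes weighted by
#'     inverse log-degree}
#'   \item{SO, SA, LHN, HP, HD}{the endpoint degree normalisation of the
#'     local index applied to K instead of A^2, e.g.
#'     SO_G(u,v) = 2 K(u,v)/(d_u + d_v)}
#' }
#' When the series diverges the convergence policy of \code{params} decides
#' between an error and truncated-series fallback (result flagged via the
#' \code{truncated} attribute).
#'
#' @param graph An undirected simple \code{igraph}.
#' @param index One of the eight extendable indices (\code{index_names(TRUE)}).
#' @param beta Damping weight in (0, 1).
#' @param params Optional \code{\link{extension_params}} (overrides
#'   \code{beta}).
#' @return A \code{link_scores} matrix with \code{family = "global"}.
#' @export
global_scores <- function(graph, index, beta = 0.001, params = NULL) {
  index <- match_index(index, extendable = TRUE)
  assert_simple_graph(graph)
  if (is.null(params)) params <- extension_params(beta = beta)
  params <- as_extension_params(params)
  w <- propagator_matrix(graph, index)
  rho <- spectral_radius(w)
  if (params$beta * rho >= 1 - 1e-12) {
    if (params$convergence_policy == "error") {
      stop(sprintf("walk series for %s_G diverges: beta * rho(W) = %g * %g >= 1",
                   index, params$beta, rho))
    }
    warning(sprintf(
      "walk series for %s_G diverges (beta * rho(W) = %.4g); truncating at walk length L = %d",
      index, params$beta * rho, params$truncation_order))
    return(truncated_global_scores(graph, index, params = params))
  }
  a <- adjacency_matrix(graph, sparse = FALSE)
  s <- if (index %in% c("RA", "AA")) {
    # A * (beta W + beta^2 W^2 + ...) with W = D^-1 A (or its log variant)
    # is the closed form A (I - beta W)^-1 - A.
    a %*% resolvent_series(w, params$beta)
  } else {
    degree_normalise(resolvent_series(a, params$beta), graph, index)
  }
  new_link_scores(s, index, "global", beta = params$beta, truncated = FALSE)
}

# Endpoint degree normalisation shared by the CN-family indices, applied to
# any walk-count matrix m (A^2 for local, A^2 + beta A^3 for quasi-local,
# the Katz matrix for global). 0/0 -> 0.
degree_normalise <- function(m, graph, index) {
  if (index == "CN") {
    return(m)
  }
  k <- degree_weights(graph, "degree")
  denom <- switch(index,
    SO = outer(k, k, `+`) / 2,
    SA = sqrt(outer(k, k)),
    LHN = outer(k, k),
    HP = outer(k, k, pmin),
    HD = outer(k, k, pmax)
  )
  safe_divide(m, denom)
}

#' Quasi-local walk-series similarity scores
#'
#' The first two terms of each index's global walk series — walks of length
#' two and three — trading a little accuracy for much lower cost than the
#' full resolvent:
#' \describe{
#'   \item{CN}{A^2 + beta A^3 (the LP index)}
#'   \item{RA}{A D^-1 A + beta A D^-1 A D^-1 A}
#'   \item{AA}{the same with (log D)^-1}
#'   \item{SO, SA, LHN, HP, HD}{endpoint degree normalisation of
#'     A^2 + beta A^3}
#' }
#' Note the printed quasi-local forms carry no leading beta on the first
#' term, unlike the global series whose first term is beta^1; rankings are
#' unaffected because AUC is invariant to per-index scaling.
#'
#' @inheritParams global_scores
#' @return A \code{link_scores} matrix with \code{family = "quasi-local"}.
#' @examples
#' g <- canonical_graph("path", 3)
#' quasi_local_scores(g, "RA", beta = 0.1)[1, 3] # 0.5
#' @export
quasi_local_scores <- function(graph, index, beta = 0.001, params = NULL) {
  index <- match_index(index, extendable = TRUE)
  assert_simple_graph(graph)
  if (is.null(params)) params <- extension_params(beta = beta)
  params <- as_extension_params(params)
  beta <- params$beta
  a <- adjacency_matrix(graph, sparse = FALSE)
  s <- if (index %in% c("RA", "AA")) {
    wa <- switch(index,
      RA = degree_weights(graph, "inverse") * a,
      AA = degree_weights(graph, "log-inverse") * a
    )
    first <- a %*% wa
    first + beta * (first %*% wa)
  } else {
    a2 <- a %*% a
    degree_normalise(a2 + beta * (a2 %*% a), graph, index)
  }
  new_link_scores(s, index, "quasi-local", beta = beta)
}

#' Truncated global walk-series scores
#'
#' Partial sum of an index's global series up to walk length L — the
#' explicit fallback used when the closed form diverges, and a diagnostic
#' for how fast the series converges. For the CN family this is
#' sum_{l=1}^{L} beta^l A^l with the index's endpoint degree normalisation;
#' for RA/AA it is sum_{k=1}^{L-1} beta^k A W^k (walk length k+1) with W the
#' index's propagator.
#'
#' @inheritParams global_scores
#' @param truncation_order Maximum walk length L >= 2.
#' @return A \code{link_scores} matrix flagged \code{truncated = TRUE}.
#' @export
truncated_global_scores <- function(graph, index, beta = 0.001,
                                    truncation_order = 10L, params = NULL) {
  index <- match_index(index, extendable = TRUE)
  assert_simple_graph(graph)
  if (is.null(params)) {
    params <- extension_params(beta = beta, truncation_order = truncation_order)
  }
  params <- as_extension_params(params)
  beta <- params$beta
  L <- params$truncation_order
  a <- adjacency_matrix(graph, sparse = FALSE)
  s <- if (index %in% c("RA", "AA")) {
    w <- propagator_matrix(graph, index)
    a %*% partial_series(w, beta, L - 1L)
  } else {
    degree_normalise(partial_series(a, beta, L), graph, index)
  }
  new_link_scores(s, index, "global", beta = beta, truncated = TRUE)
}

#' Score all node pairs with any index/family combination
#'
#' Single dispatch point used by the evaluation harness and the command-line
#' interface: local indices take no parameters; quasi-local and global
#' extensions are parameterised by \code{params}.
#'
#' @param graph An undirected simple \code{igraph}.
#' @param index Index name; PA and JACCARD are local-only.
#' @param family \code{"local"}, \code{"quasi-local"} or \code{"global"}.
#' @param params An \code{\link{extension_params}} object (ignored for
#'   local).
#' @return A \code{link_scores} matrix.
#' @export
score_links <- function(graph, index,
                        family = c("local", "quasi-local", "global"),
                        params = extension_params()) {
  family <- match.arg(family)
  switch(family,
    "local" = local_scores(graph, index),
    "quasi-local" = quasi_local_scores(graph, index, params = params),
    "global" = global_scores(graph, index, params = params)
  )
}
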