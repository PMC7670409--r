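#' Similarity index vocabulary
#'
#' The local indices available in the package. The eight degree-aware
#' indices (CN, RA, AA, SO, SA, LHN, HP, HD) all have quasi-local and global
#' extensions; PA (preferential attachment) and JACCARD are local-only
#' baselines.
#'
#' @param extendable If \code{TRUE}, return only the eight indices with
#'   quasi-local/global extensions.
#' @return Character vector of index names.
#' @export
index_names <- function(extendable = FALSE) {
  base <- c("CN", "RA", "AA", "SO", "SA", "LHN", "HP", "HD")
  if (extendable) base else c(base, "PA", "JACCARD")
}

match_index <- function(index, extendable = FALSE) {
  if (length(index) != 1L || !is.character(index)) {
    stop("index must be a single character name")
  }
  up <- toupper(index)
  ok <- index_names(extendable)
  if (!up %in% ok) {
    stop("unknown similarity index '", index, "'; available: ",
         paste(ok, collapse = ", "))
  }
  up
}

# Wrap a symmetric score matrix with its metadata. The diagonal is forced
# to zero: self-pairs are never candidate links.
new_link_scores <- function(m, index, family, beta = NA_real_, truncated = FALSE) {
  m <- as.matrix(m)
  diag(m) <- 0
  labs <- if (!is.null(rownames(m))) rownames(m) else colnames(m)
  dimnames(m) <- if (is.null(labs)) NULL else list(labs, labs)
  structure(m,
    class = c("link_scores", "matrix", "array"),
    index = index, family = family, beta = beta, truncated = truncated
  )
}

#' @export
print.link_scores <- function(x, ...) {
  fam <- attr(x, "family")
  beta <- attr(x, "beta")
  cat(sprintf("<link_scores> %s (%s%s) over %d nodes%s\n",
              attr(x, "index"), fam,
              if (is.finite(beta)) sprintf(", beta = %g", beta) else "",
              nrow(x),
              if (isTRUE(attr(x, "truncated"))) " [truncated series]" else ""))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Extract non-edge pair scores, ranked
#'
#' Returns the candidate (non-adjacent, non-self) pairs of a graph together
#' with their similarity scores, in descending score order — the ranking a
#' link-prediction practitioner would act on. Ties are broken by pair index
#' order for determinism.
#'
#' @param scores A \code{link_scores} matrix.
#' @param graph The graph the scores were computed from (defines which pairs
#'   are already linked and thus excluded).
#' @return A data frame with columns \code{u}, \code{v}, \code{score}.
#' @export
ranked_candidates <- function(scores, graph) {
  stopifnot(inherits(scores, "link_scores"))
  a <- adjacency_matrix(graph, sparse = FALSE)
  stopifnot(nrow(a) == nrow(scores))
  ut <- upper.tri(a)
  keep <- ut & a == 0
  ij <- which(keep, arr.ind = TRUE)
  s <- unclass(scores)[keep]
  ord <- order(-s, ij[, 1], ij[, 2])
  labs <- node_labels(graph)
  data.frame(
    u = labs[ij[ord, 1]],
    v = labs[ij[ord, 2]],
    score = s[ord],
    stringsAsFactors = FALSE
  )
}
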