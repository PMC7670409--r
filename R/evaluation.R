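#' Split observed links into training and probe sets
#'
#' Randomly partitions the edge set E into a training set E^T and a probe
#' set E^P. Scores are later computed from the training graph only and
#' evaluated on the probe links. The node set is preserved: endpoints whose
#' edges all land in the probe set remain in the training graph as isolated
#' nodes, so score matrices keep their dimensions across splits.
#'
#' The probe size is round(probe_fraction * |E|) with half rounded away
#' from zero, clamped to [1, |E| - 1]. The split is deterministic for a
#' fixed seed.
#'
#' @param graph An undirected simple \code{igraph} with >= 2 edges.
#' @param probe_fraction Fraction of edges assigned to the probe set, in
#'   (0, 1).
#' @param seed Integer RNG seed.
#' @return An object of class \code{edge_split}: list with \code{graph}
#'   (the full graph), \code{train} (training graph, full node set),
#'   \code{train_edges} and \code{probe_edges} (2-column vertex-index
#'   matrices, smaller index first), \code{probe_fraction}, \code{seed}.
#' @export
split_edges <- function(graph, probe_fraction, seed) {
  assert_simple_graph(graph)
  if (!is.numeric(probe_fraction) || probe_fraction <= 0 || probe_fraction >= 1) {
    stop("probe_fraction must lie strictly between 0 and 1")
  }
  m <- igraph::ecount(graph)
  if (m < 2L) {
    stop("edge splitting requires at least 2 edges")
  }
  el <- igraph::as_edgelist(graph, names = FALSE)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  n_probe <- floor(probe_fraction * m + 0.5) # round half away from zero
  n_probe <- min(max(n_probe, 1L), m - 1L)
  set.seed(seed)
  probe_idx <- sample.int(m, n_probe)
  train <- igraph::subgraph_from_edges(graph, setdiff(seq_len(m), probe_idx),
                                       delete.vertices = FALSE)
  structure(list(
    graph = graph,
    train = train,
    train_edges = el[-probe_idx, , drop = FALSE],
    probe_edges = el[probe_idx, , drop = FALSE],
    probe_fraction = probe_fraction,
    seed = as.integer(seed)
  ), class = "edge_split")
}

#' @export
print.edge_split <- function(x, ...) {
  cat(sprintf("<edge_split> %d training / %d probe edges (fraction %.2f, seed %d)\n",
              nrow(x$train_edges), nrow(x$probe_edges), x$probe_fraction, x$seed))
  invisible(x)
}

#' Nonexistent links of a graph
#'
#' The candidate set E' = U \ E: all unordered node pairs that are not
#' observed links, over the full node set. When evaluating a split, E' is
#' always taken against the full edge set, so probe links never appear
#' among the candidates.
#'
#' @param graph An undirected simple \code{igraph}.
#' @return A 2-column matrix of vertex indices (smaller first), one row per
#'   nonexistent link.
#' @export
candidate_pairs <- function(graph) {
  a <- adjacency_matrix(graph, sparse = FALSE)
  ij <- which(upper.tri(a) & a == 0, arr.ind = TRUE)
  colnames(ij) <- NULL
  ij[, c(1, 2), drop = FALSE]
}

# Linear indices of (i, j) pairs into an n x n matrix.
pair_lin <- function(pairs, n) {
  (pairs[, 2] - 1L) * n + pairs[, 1]
}

#' AUC of a link-prediction scoring
#'
#' The probability that a randomly chosen probe link scores higher than a
#' randomly chosen nonexistent link, with ties credited 0.5:
#' AUC = (n' + 0.5 n'') / n, where over n comparisons the probe link wins
#' n' times and ties n'' times. Exhaustive mode performs every
#' (probe, nonexistent) comparison, n = |E^P| |E'|, and equals the
#' normalised Mann-Whitney rank statistic; sampled mode draws n comparison
#' pairs independently with replacement. A scorer that assigns i.i.d.
#' random scores attains AUC 0.5 in expectation.
#'
#' @param scores A \code{link_scores} matrix computed from the training
#'   graph of \code{split}.
#' @param split An \code{\link{split_edges}} result.
#' @param candidates Optional precomputed \code{\link{candidate_pairs}} of
#'   the full graph (recomputed when \code{NULL}).
#' @param mode \code{"auto"} (exhaustive up to 1e7 comparisons, sampled
#'   beyond), \code{"exhaustive"}, or \code{"sampled"}.
#' @param n_samples Number of comparisons in sampled mode.
#' @param seed RNG seed for sampled mode.
#' @return An object of class \code{auc_result}: list with \code{auc},
#'   \code{n}, \code{n_wins}, \code{n_ties}, \code{mode}.
#' @export
auc_score <- function(scores, split, candidates = NULL,
                      mode = c("auto", "exhaustive", "sampled"),
                      n_samples = 1e5, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(split, "edge_split"))
  n <- igraph::vcount(split$graph)
  if (nrow(scores) != n) {
    stop("score matrix dimension does not match the graph")
  }
  if (is.null(candidates)) {
    candidates <- candidate_pairs(split$graph)
  }
  if (nrow(split$probe_edges) == 0L || nrow(candidates) == 0L) {
    stop("AUC requires non-empty probe and candidate sets")
  }
  s <- unclass(scores)
  probe_s <- s[pair_lin(split$probe_edges, n)]
  cand_s <- s[pair_lin(candidates, n)]
  if (mode == "auto") {
    mode <- if (length(probe_s) * length(cand_s) <= 1e7) "exhaustive" else "sampled"
  }
  if (mode == "exhaustive") {
    cs <- sort(cand_s)
    leq <- findInterval(probe_s, cs)
    less <- findInterval(probe_s, cs, left.open = TRUE)
    # left.open counts strictly-smaller candidates; the difference is ties
    wins <- sum(less)
    ties <- sum(leq - less)
    total <- length(probe_s) * length(cand_s)
  } else {
    set.seed(seed)
    ps <- probe_s[sample.int(length(probe_s), n_samples, replace = TRUE)]
    cs <- cand_s[sample.int(length(cand_s), n_samples, replace = TRUE)]
    wins <- sum(ps > cs)
    ties <- sum(ps == cs)
    total <- n_samples
  }
  structure(list(
    auc = (wins + 0.5 * ties) / total,
    n = total, n_wins = wins, n_ties = ties, mode = mode
  ), class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f  (%s; n = %g, wins = %g, ties = %g)\n",
              x$auc, x$mode, x$n, x$n_wins, x$n_ties))
  invisible(x)
}

#' Precision of the top-L ranked pairs
#'
#' Ranks the pool E^P union E' (probe links plus nonexistent links) by
#' score and reports the fraction of the top L that are true probe links.
#' Ties are broken deterministically by pair index order.
#'
#' @inheritParams auc_score
#' @param L Number of top-ranked pairs to inspect (1 <= L <= pool size).
#' @return A fraction in [0, 1].
#' @export
precision_at_l <- function(scores, split, L, candidates = NULL) {
  stopifnot(inherits(split, "edge_split"))
  n <- igraph::vcount(split$graph)
  if (is.null(candidates)) {
    candidates <- candidate_pairs(split$graph)
  }
  pool_lin <- c(pair_lin(split$probe_edges, n), pair_lin(candidates, n))
  is_probe <- c(rep(TRUE, nrow(split$probe_edges)), rep(FALSE, nrow(candidates)))
  if (L < 1 || L > length(pool_lin)) {
    stop("L must lie between 1 and the ranking pool size (", length(pool_lin), ")")
  }
  s <- unclass(scores)[pool_lin]
  top <- order(-s, pool_lin)[seq_len(L)]
  mean(is_probe[top])
}

#' Random baseline scores
#'
#' Assigns every node pair an i.i.d. uniform(0, 1) score. Chance-level
#' scoring: its expected AUC is 0.5, which makes it the standard
#' calibration baseline for the evaluation protocol.
#'
#' @param graph An undirected simple \code{igraph}.
#' @param seed Integer RNG seed.
#' @return A \code{link_scores} matrix.
#' @export
random_scores <- function(graph, seed) {
  n <- igraph::vcount(graph)
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  new_link_scores(m, "RANDOM", "baseline")
}

#' Repeated train/probe evaluation of one index
#'
#' The standard experimental protocol: repeat \code{repetitions} times an
#' independent random split of the observed links, recompute scores on the
#' training graph only, and evaluate AUC; report per-run values with their
#' mean and standard deviation. Run r uses seed \code{base_seed + r}, so a
#' report is bit-reproducible, and different indices evaluated with the
#' same \code{base_seed} and \code{probe_fraction} see identical splits.
#'
#' @param graph An undirected simple \code{igraph}.
#' @param index Index name.
#' @param family \code{"local"}, \code{"quasi-local"} or \code{"global"}.
#' @param params \code{\link{extension_params}} for the extension families.
#' @param probe_fraction Probe fraction (default 0.1, the standard 90/10
#'   protocol).
#' @param repetitions Number of independent splits (default 100).
#' @param base_seed Base RNG seed.
#' @param auc_mode,n_samples Passed to \code{\link{auc_score}}.
#' @return An object of class \code{experiment_report}: list with
#'   \code{runs} (data frame: rep, seed, auc), \code{mean}, \code{sd} and
#'   \code{config}.
#' @export
run_experiment <- function(graph, index, family = "local",
                           params = extension_params(),
                           probe_fraction = 0.1, repetitions = 100L,
                           base_seed = 42L, auc_mode = "auto",
                           n_samples = 1e5) {
  stopifnot(repetitions >= 1)
  candidates <- candidate_pairs(graph)
  aucs <- numeric(repetitions)
  seeds <- base_seed + seq_len(repetitions)
  for (r in seq_len(repetitions)) {
    split <- split_edges(graph, probe_fraction, seed = seeds[r])
    sc <- score_links(split$train, index, family, params)
    aucs[r] <- auc_score(sc, split, candidates,
                         mode = auc_mode, n_samples = n_samples,
                         seed = seeds[r])$auc
  }
  structure(list(
    runs = data.frame(rep = seq_len(repetitions), seed = seeds, auc = aucs),
    mean = mean(aucs),
    sd = stats::sd(aucs),
    config = list(index = match_index(index), family = family,
                  beta = params$beta, probe_fraction = probe_fraction,
                  repetitions = repetitions, base_seed = base_seed)
  ), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s (%s, beta = %g): AUC = %.4f +/- %.4f over %d runs (probe %.0f%%)\n",
              cfg$index, cfg$family, cfg$beta, x$mean,
              ifelse(is.na(x$sd), 0, x$sd), cfg$repetitions,
              100 * cfg$probe_fraction))
  invisible(x)
}

#' Factorial sweep over indices, families, probe sizes and beta
#'
#' Evaluates every combination in the grid. Within each (probe fraction,
#' repetition) cell all indices, families and beta values share the same
#' train/probe split, so methods are compared on identical data. The
#' default grids follow the standard protocol: probe fractions 10-50% and
#' beta in {0.001, 0.005, 0.01, 0.05, 0.1}.
#'
#' @param graph An undirected simple \code{igraph}.
#' @param indices Character vector of index names.
#' @param families Character vector from
#'   \{"local", "quasi-local", "global"\}.
#' @param probe_fractions Numeric vector of probe fractions.
#' @param betas Numeric vector of damping weights.
#' @param repetitions Splits per cell.
#' @param base_seed Base RNG seed.
#' @param convergence_policy,truncation_order Passed to
#'   \code{\link{extension_params}}.
#' @param auc_mode,n_samples Passed to \code{\link{auc_score}}.
#' @return A long-format data frame with columns \code{index},
#'   \code{family}, \code{beta}, \code{probe_fraction}, \code{rep},
#'   \code{split_seed}, \code{auc}.
#' @export
sweep_experiments <- function(graph, indices, families = "local",
                              probe_fractions = seq(0.1, 0.5, by = 0.1),
                              betas = c(0.001, 0.005, 0.01, 0.05, 0.1),
                              repetitions = 10L, base_seed = 42L,
                              convergence_policy = "truncate",
                              truncation_order = 10L,
                              auc_mode = "auto", n_samples = 1e5) {
  stopifnot(length(indices) > 0, length(families) > 0,
            length(probe_fractions) > 0, length(betas) > 0)
  candidates <- candidate_pairs(graph)
  out <- vector("list", 0L)
  for (fi in seq_along(probe_fractions)) {
    f <- probe_fractions[fi]
    for (r in seq_len(repetitions)) {
      split_seed <- base_seed + (fi - 1L) * repetitions + r
      split <- split_edges(graph, f, seed = split_seed)
      for (beta in betas) {
        params <- extension_params(beta = beta,
                                   truncation_order = truncation_order,
                                   convergence_policy = convergence_policy)
        for (index in indices) {
          for (family in families) {
            sc <- score_links(split$train, index, family, params)
            auc <- auc_score(sc, split, candidates, mode = auc_mode,
                             n_samples = n_samples, seed = split_seed)$auc
            out[[length(out) + 1L]] <- data.frame(
              index = match_index(index), family = family, beta = beta,
              probe_fraction = f, rep = r, split_seed = split_seed,
              auc = auc, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Aggregate a sweep into mean and standard deviation per cell
#'
#' @param results Long-format data frame from
#'   \code{\link{sweep_experiments}}.
#' @return Data frame with one row per (index, family, beta,
#'   probe_fraction) cell and columns \code{mean_auc}, \code{sd_auc},
#'   \code{n_runs}.
#' @export
summarise_sweep <- function(results) {
  agg <- stats::aggregate(auc ~ index + family + beta + probe_fraction,
                          data = results,
                          FUN = function(x) c(mean(x), stats::sd(x), length(x)))
  out <- agg[, c("index", "family", "beta", "probe_fraction")]
  out$mean_auc <- agg$auc[, 1]
  out$sd_auc <- agg$auc[, 2]
  out$n_runs <- agg$auc[, 3]
  out
}
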