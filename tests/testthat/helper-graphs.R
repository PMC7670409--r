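# Shared fixtures and independent oracles for the test suite.

path3 <- function() canonical_graph("path", 3)

# Write an edge list to a temp file and return its path.
tmp_edgelist <- function(lines) {
  f <- tempfile(fileext = ".edgelist")
  writeLines(lines, f)
  f
}

karate_path <- function() {
  system.file("extdata", "karate.edgelist", package = "pathlink")
}

# Independent walk-series oracle: sum_{l=1}^{L} beta^l W^l by repeated
# multiplication, sharing no code with the package's Horner recursion.
series_oracle <- function(w, beta, L) {
  acc <- matrix(0, nrow(w), ncol(w))
  p <- diag(nrow(w))
  for (l in seq_len(L)) {
    p <- p %*% w
    acc <- acc + beta^l * p
  }
  acc
}

# Exhaustive walk enumeration of length k between u and v by depth-first
# recursion over neighbours — the from-first-principles check on A^k.
count_walks <- function(graph, u, v, k) {
  if (k == 0) return(as.integer(u == v))
  nb <- as.integer(igraph::neighbors(graph, u))
  sum(vapply(nb, function(w) count_walks(graph, w, v, k - 1), numeric(1)))
}

# Brute-force Mann-Whitney AUC: compare every probe score against every
# candidate score with an explicit double loop.
auc_bruteforce <- function(probe_s, cand_s) {
  wins <- 0
  ties <- 0
  for (p in probe_s) {
    for (c in cand_s) {
      if (p > c) wins <- wins + 1 else if (p == c) ties <- ties + 1
    }
  }
  (wins + 0.5 * ties) / (length(probe_s) * length(cand_s))
}

# Spearman rank correlation of two score vectors.
spearman <- function(x, y) suppressWarnings(stats::cor(x, y, method = "spearman"))

# Fraction of strictly ordered reference pairs that a second scoring orders
# the same way. Reference gaps below the floor are treated as ties (they are
# floating-point noise between mathematically equal scores), so a value of 1
# means the second ranking refines the reference ranking without ever
# contradicting it.
strict_concordance <- function(ext, ref, gap_floor = 1e-9) {
  dr <- outer(ref, ref, `-`)
  de <- outer(ext, ext, `-`)
  strict <- abs(dr) > gap_floor
  mean(sign(de[strict]) == sign(dr[strict]))
}

# Upper-triangle values at non-adjacent pairs (candidate pairs) of a graph.
candidate_values <- function(scores, graph) {
  a <- adjacency_matrix(graph, sparse = FALSE)
  keep <- upper.tri(a) & a == 0
  unclass(scores)[keep]
}
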