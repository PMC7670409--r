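test_that("Katz scores match closed-form micro-examples and the damped series", {
  g <- path3()
  expect_equal(katz_scores(g, beta = 0.1)[1, 3], 0.01 / 0.98, tolerance = 1e-12)

  # single edge: sum of odd powers of beta is a geometric series
  k2 <- canonical_graph("path", 2)
  expect_equal(katz_scores(k2, beta = 0.5)[1, 2], 2 / 3, tolerance = 1e-12)

  # cross-check against the independent truncated-series oracle
  a <- adjacency_matrix(g, sparse = FALSE)
  so <- series_oracle(a, 0.1, 50)
  diag(so) <- 0 # self-pairs are excluded from scoring
  expect_equal(unclass(katz_scores(g, beta = 0.1)), so,
               tolerance = 1e-12, ignore_attr = TRUE)

  # leading-order behaviour as beta -> 0: beta^2 A^2 off the edges,
  # beta A on the edges
  g <- erdos_renyi_graph(15, 0.3, seed = 9)
  a <- adjacency_matrix(g, sparse = FALSE)
  k <- unclass(katz_scores(g, beta = 1e-8))
  a2 <- a %*% a
  non_adj <- upper.tri(a) & a == 0
  expect_equal(k[non_adj] / 1e-16, a2[non_adj], tolerance = 1e-5)
  adj <- upper.tri(a) & a == 1
  expect_equal(k[adj] / 1e-8, a[adj], tolerance = 1e-5)
})

test_that("local-path index counts damped length-3 walks", {
  g <- path3()
  expect_equal(lp_scores(g, beta = 0.3)[1, 3], 1) # A^3 entry vanishes by parity

  tri <- canonical_graph("cycle", 3)
  expect_equal(lp_scores(tri, beta = 0.1)[1, 2], 1 + 0.1 * 3) # A^2 = 1, A^3 = 3

  # beta -> 0 reduces LP to the common-neighbour ranking: every pair CN
  # orders strictly stays ordered the same way (LP only refines CN ties)
  g <- erdos_renyi_graph(25, 0.2, seed = 12)
  lp <- candidate_values(lp_scores(g, beta = 1e-9), g)
  cn <- candidate_values(local_scores(g, "CN"), g)
  expect_equal(strict_concordance(lp, cn), 1)
})

test_that("global extensions match hand-derived path-graph values", {
  g <- path3()
  expect_equal(global_scores(g, "RA", beta = 0.1)[1, 3], 0.05 / 0.99,
               tolerance = 1e-12)
  # SO_G(a,c) = 2 K(a,c) / (d_a + d_c) with leaf degrees 1
  expect_equal(global_scores(g, "SO", beta = 0.1)[1, 3], 0.01 / 0.98,
               tolerance = 1e-12)
})

test_that("quasi-local extensions match hand-derived values and the truncated series", {
  g <- path3()
  # second term vanishes by parity
  expect_equal(quasi_local_scores(g, "RA", beta = 0.1)[1, 3], 0.5)

  # quasi-local = first two terms of the global series, rescaled by beta
  g <- erdos_renyi_graph(30, 0.2, seed = 7)
  a <- adjacency_matrix(g, sparse = FALSE)
  beta <- 0.001
  for (idx in c("RA", "AA")) {
    w <- propagator_matrix(g, idx)
    two_terms <- a %*% series_oracle(w, beta, 2) / beta
    diag(two_terms) <- 0
    ql <- unclass(quasi_local_scores(g, idx, beta = beta))
    expect_equal(ql, two_terms, tolerance = 1e-9, ignore_attr = TRUE)
  }

  # beta -> 0: every quasi-local index collapses to its local matrix form
  for (idx in index_names(extendable = TRUE)) {
    ql <- unclass(quasi_local_scores(g, idx, beta = 1e-12))
    loc <- unclass(local_scores(g, idx))
    expect_equal(ql, loc, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("closed-form resolvents equal the truncated series in the convergent regime", {
  g <- erdos_renyi_graph(30, 0.2, seed = 7)
  a <- adjacency_matrix(g, sparse = FALSE)
  beta <- 0.001
  for (idx in c("CN", "RA", "AA")) {
    w <- propagator_matrix(g, idx)
    expect_lt(beta * spectral_radius(w), 0.9)
    closed <- unclass(global_scores(g, idx, beta = beta))
    series <- if (idx == "CN") series_oracle(w, beta, 60) else
      a %*% series_oracle(w, beta, 60) # A(beta W + ... + beta^60 W^60)
    diag(series) <- 0
    expect_equal(closed, series, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("degree-normalised global forms equal the literal element-wise expressions", {
  # Table-style element-wise construction: D M^(-ew) + M^(-ew) D, inverted
  # element-wise again, with the 0 -> 0 convention.
  ew_inv <- function(m) ifelse(m != 0, 1 / m, 0)
  g <- erdos_renyi_graph(25, 0.25, seed = 14)
  beta <- 0.01
  a <- adjacency_matrix(g, sparse = FALSE)
  n <- nrow(a)
  d <- diag(as.numeric(igraph::degree(g)))
  k <- solve(diag(n) - beta * a) - diag(n)
  mi <- ew_inv(k)
  expected <- list(
    SO = 2 * ew_inv(d %*% mi + mi %*% d),
    HP = ew_inv(pmin(d %*% mi, mi %*% d)),
    HD = ew_inv(pmax(d %*% mi, mi %*% d)),
    SA = diag(1 / sqrt(pmax(diag(d), 1))) %*% k %*% diag(1 / sqrt(pmax(diag(d), 1)))
  )
  for (idx in names(expected)) {
    got <- unclass(global_scores(g, idx, beta = beta))
    diag(expected[[idx]]) <- 0
    expect_equal(got, expected[[idx]], tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("rankings of extensions converge to the local ranking as beta -> 0", {
  # In the small-damping limit an extension refines its local index's
  # ranking: strictly ordered local pairs keep their order, and only tie
  # groups (shared by rank correlation's tie handling) are resolved.
  for (s in c(3, 17)) {
    g <- erdos_renyi_graph(30, 0.15, seed = s)
    for (idx in c("CN", "RA", "AA", "SA", "HD")) {
      loc <- candidate_values(local_scores(g, idx), g)
      ql <- candidate_values(quasi_local_scores(g, idx, beta = 1e-8), g)
      gl <- candidate_values(global_scores(g, idx, beta = 1e-8), g)
      expect_equal(strict_concordance(ql, loc), 1)
      expect_equal(strict_concordance(gl, loc), 1)
      # rank correlation approaches its tie-limited ceiling from below
      gl_big <- candidate_values(global_scores(g, idx, beta = 0.05), g)
      expect_gte(spearman(gl, loc) + 1e-9, spearman(gl_big, loc))
    }
  }
})

test_that("spectral radius matches known spectra", {
  expect_equal(spectral_radius(adjacency_matrix(canonical_graph("complete", 6),
                                                sparse = FALSE)), 5,
               tolerance = 1e-6)
  expect_equal(spectral_radius(adjacency_matrix(path3(), sparse = FALSE)),
               sqrt(2), tolerance = 1e-6)
  # row-stochastic propagator of a connected graph has radius 1
  g <- erdos_renyi_graph(20, 0.4, seed = 2)
  expect_equal(spectral_radius(propagator_matrix(largest_component(g), "RA")), 1,
               tolerance = 1e-6)
  expect_error(spectral_radius(matrix(1, 2, 3)), "square")
})

test_that("the RA propagator series converges for every beta below one", {
  g <- largest_component(erdos_renyi_graph(25, 0.2, seed = 4))
  for (beta in c(0.001, 0.005, 0.01, 0.05, 0.1, 0.9)) {
    expect_no_warning(expect_no_error(
      global_scores(g, "RA", params = extension_params(beta = beta,
                                                       convergence_policy = "error"))
    ))
  }
})

test_that("divergent series trigger the convergence policy", {
  g <- canonical_graph("complete", 6) # rho(A) = 5, so beta = 0.5 diverges
  expect_error(
    global_scores(g, "CN", params = extension_params(0.5, convergence_policy = "error")),
    "diverges"
  )
  expect_warning(
    s <- global_scores(g, "CN", params = extension_params(0.5, truncation_order = 8)),
    "truncating"
  )
  expect_true(attr(s, "truncated"))
  a <- adjacency_matrix(g, sparse = FALSE)
  expect_equal(unclass(s), {
    o <- series_oracle(a, 0.5, 8); diag(o) <- 0; o
  }, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("explicit truncation reproduces local and LP orderings at small depth", {
  g <- erdos_renyi_graph(25, 0.2, seed = 21)
  beta <- 0.01
  # L = 2: only the A^2 term survives on non-adjacent pairs
  t2 <- candidate_values(truncated_global_scores(g, "CN", beta, 2), g)
  cn <- candidate_values(local_scores(g, "CN"), g)
  expect_equal(t2, beta^2 * cn, tolerance = 1e-12)
  # L = 3 equals LP up to the global leading factor beta^2
  t3 <- candidate_values(truncated_global_scores(g, "CN", beta, 3), g)
  lp <- candidate_values(lp_scores(g, beta), g)
  expect_equal(t3, beta^2 * lp, tolerance = 1e-12)
  # convergent regime: L = 30 approximates the closed form
  t30 <- unclass(truncated_global_scores(g, "CN", 0.001, 30))
  closed <- unclass(global_scores(g, "CN", 0.001))
  expect_equal(t30, closed, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("all score families stay symmetric, finite and non-negative over the beta sweep", {
  g <- largest_component(erdos_renyi_graph(30, 0.2, seed = 11))
  for (beta in c(0.001, 0.005, 0.01, 0.05, 0.1)) {
    for (idx in c("CN", "RA", "AA", "SO", "HP")) {
      for (fam in c("quasi-local", "global")) {
        rho <- spectral_radius(propagator_matrix(g, idx))
        if (fam == "global" && beta * rho >= 1) next
        s <- unclass(score_links(g, idx, fam, extension_params(beta = beta)))
        expect_true(all(is.finite(s)))
        expect_true(all(s >= 0))
        expect_equal(s, t(s))
      }
    }
  }
})

test_that("extension parameters are validated", {
  expect_error(extension_params(beta = 0), "beta")
  expect_error(extension_params(beta = 1), "beta")
  expect_error(extension_params(beta = 0.1, truncation_order = 1), "truncation_order")
  expect_error(global_scores(path3(), "PA", beta = 0.1), "unknown similarity index")
})
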