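test_that("connectivity construction follows the stated rules", {
  set.seed(1)
  X <- matrix(stats::rnorm(20 * 4), 20, 4)
  X[, 2] <- X[, 1]            # identical pair -> edge 1
  X[, 4] <- -X[, 3]           # anticorrelated pair -> zeroed
  C <- build_connectivity(X)
  expect_equal(C[1, 2], 1, tolerance = 1e-12)
  expect_equal(C[3, 4], 0)
  expect_equal(diag(C), rep(0, 4), ignore_attr = TRUE)
  expect_true(all(C >= 0 & C <= 1))
  X[, 3] <- 5                 # zero-variance region
  expect_warning(C2 <- build_connectivity(X), "zero-variance")
  expect_true(all(C2[3, ] == 0))
})

test_that("latent-factor groups give mean off-diagonal weight near rho^2", {
  rho <- 0.6
  spec <- cohort_spec(group_sizes = c(G = 35L, H = 35L),
                      block_sizes = c(m = 40L, APOE = 2L),
                      effect_size = 0, covariance_strength = rho, seed = 2)
  co <- generate_cohort(spec)
  C <- build_connectivity(co$blocks$m[co$labels == "G", ])
  off <- C[upper.tri(C)]
  expect_lt(abs(mean(off) - rho^2), 0.05)
})

test_that("functional connectivity Fisher-averages per-subject matrices", {
  set.seed(3)
  ts_list <- lapply(1:5, function(i) {
    base <- matrix(stats::rnorm(6 * 60), 6, 60)
    base[2, ] <- base[1, ] + stats::rnorm(60, sd = 0.3)   # strong pair
    base
  })
  C <- build_connectivity(ts_list, source = "timeseries_functional")
  expect_gt(C[1, 2], 0.7)
  expect_equal(diag(C), rep(0, 6), ignore_attr = TRUE)
})

test_that("density thresholding keeps the exact edge count with stable ties", {
  set.seed(4)
  C <- matrix(stats::runif(100), 10); C <- (C + t(C)) / 2; diag(C) <- 0
  g <- threshold_by_density(C, 0.20)
  expect_equal(attr(g, "n_edges"), 9)          # round(0.2 * 45)
  expect_equal(sum(g) / 2, 9)
  expect_true(all(g == t(g)) && all(diag(g) == 0))
  expect_error(threshold_by_density(C, 0.001), "zero edges")
  # permutation invariance when all weights are distinct
  perm <- sample(10)
  gp <- threshold_by_density(C[perm, perm], 0.20)
  expect_equal(unclass(gp), unclass(g)[perm, perm], ignore_attr = TRUE)
  # high density recovers the support of a sparse matrix
  Cs <- matrix(0, 6, 6); Cs[1, 2] <- Cs[2, 1] <- 0.9; Cs[3, 4] <- Cs[4, 3] <- 0.5
  gs <- threshold_by_density(Cs, 2 / 15)
  expect_equal(sum(gs) / 2, 2)
  expect_equal(gs[1, 2] + gs[3, 4], 2)
})

test_that("the 5-25% sweep yields 41 graphs with non-decreasing edges", {
  set.seed(5)
  C <- matrix(stats::runif(40 * 40), 40); C <- (C + t(C)) / 2; diag(C) <- 0
  dens <- seq(0.05, 0.25, by = 0.005)
  expect_length(dens, 41)
  edges <- vapply(dens, function(d) sum(threshold_by_density(C, d)) / 2, 0)
  expect_true(all(diff(edges) >= 0))
})

test_that("canonical graphs reproduce hand-computed metrics", {
  tri <- matrix(1, 3, 3) - diag(3)
  m <- global_metrics(tri)
  expect_equal(m$transitivity, 1, tolerance = 1e-12)
  expect_equal(m$char_path_length, 1, tolerance = 1e-12)
  expect_equal(m$local_efficiency_mean, 1, tolerance = 1e-12)
  expect_equal(modularity_q(tri, rep(1, 3)), 0, tolerance = 1e-12)
  p4 <- matrix(0, 4, 4); p4[cbind(1:3, 2:4)] <- 1; p4 <- p4 + t(p4)
  m4 <- global_metrics(p4)
  expect_equal(m4$char_path_length, 5 / 3, tolerance = 1e-12)
  expect_equal(m4$transitivity, 0)
  two_tri <- matrix(0, 6, 6)
  two_tri[1:3, 1:3] <- tri; two_tri[4:6, 4:6] <- tri
  expect_equal(modularity_q(two_tri, rep(1:2, each = 3)), 0.5, tolerance = 1e-12)
  # star and handshake
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  expect_equal(nodal_degree(star), c(4L, 1L, 1L, 1L, 1L))
  expect_equal(sum(nodal_degree(star)), 2 * sum(star) / 2)
  k4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(nodal_degree(k4), rep(3L, 4))
  expect_error(global_metrics(matrix(0, 3, 3)), "no edges")
})

test_that("graph metrics agree with brute-force enumeration on random graphs", {
  set.seed(6)
  for (i in 1:30) {
    A <- random_graph(sample(5:12, 1), p = stats::runif(1, 0.15, 0.6))
    m <- global_metrics(A, seed = 1)
    bf <- bf_char_path_length(A)
    expect_equal(m$char_path_length, bf$l, tolerance = 1e-12)
    expect_equal(m$n_infinite_pairs, bf$n_inf)
    expect_equal(m$transitivity, mean(bf_local_clustering(A)), tolerance = 1e-12)
    expect_equal(m$local_efficiency, bf_local_efficiency(A), tolerance = 1e-12)
    expect_equal(m$degree, as.integer(rowSums(A)))
    # Louvain never loses to the trivial partition
    expect_gte(m$modularity, 0)
  }
})

test_that("identical groups give zero observed difference and p = 1", {
  set.seed(7)
  A <- matrix(stats::rnorm(12 * 15), 12, 15)
  r <- suppressWarnings(
    permutation_group_test(A, A, "transitivity", densities = c(0.1, 0.2),
                           n_perm = 49, seed = 1))
  expect_equal(r$table$observed, c(0, 0), tolerance = 1e-12)
  expect_equal(r$table$p, c(1, 1))
})

test_that("strong covariance contrast is detected across densities", {
  spec <- cohort_spec(group_sizes = c(G = 35L, H = 35L),
                      block_sizes = c(m = 30L, APOE = 2L),
                      effect_size = 0,
                      covariance_strength = c(G = 0.8, H = 0.0), seed = 8)
  co <- generate_cohort(spec)
  A <- co$blocks$m[co$labels == "G", ]
  B <- co$blocks$m[co$labels == "H", ]
  r <- suppressWarnings(
    permutation_group_test(A, B, "transitivity",
                           densities = seq(0.1, 0.25, by = 0.05),
                           n_perm = 99, seed = 9))
  expect_gte(mean(r$table$significant), 0.8)
})

test_that("BH adjustment matches hand computation and edge cases", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04))$adjusted, rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(fdr_adjust(0.03)$adjusted, 0.03)
  r1 <- fdr_adjust(rep(1, 5))
  expect_equal(r1$adjusted, rep(1, 5))
  expect_false(any(r1$significant))
  expect_length(fdr_adjust(numeric(0))$adjusted, 0)
})
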