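# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (exhaustive enumeration, Floyd-Warshall, dense grids)
# so they share no code path with the implementation they check.

# all-pairs shortest paths by Floyd-Warshall on a binary adjacency matrix
bf_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

bf_char_path_length <- function(adj) {
  D <- bf_distances(adj)
  off <- D[row(D) != col(D)]
  list(l = mean(off[is.finite(off)]), n_inf = sum(!is.finite(off)))
}

# local clustering by explicit triangle enumeration
bf_local_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (k in seq_len(n)) {
    nb <- which(adj[k, ] > 0)
    d <- length(nb)
    if (d < 2) next
    tri <- 0
    for (a in seq_len(d - 1)) for (b in (a + 1):d) {
      if (adj[nb[a], nb[b]] > 0) tri <- tri + 1
    }
    cc[k] <- 2 * tri / (d * (d - 1))
  }
  cc
}

bf_local_efficiency <- function(adj) {
  n <- nrow(adj)
  le <- numeric(n)
  for (k in seq_len(n)) {
    nb <- which(adj[k, ] > 0)
    d <- length(nb)
    if (d < 2) next
    Ds <- bf_distances(adj[nb, nb, drop = FALSE])
    inv <- 1 / Ds[row(Ds) != col(Ds)]
    inv[!is.finite(inv)] <- 0
    le[k] <- sum(inv) / (d * (d - 1))
  }
  le
}

# random connected-ish binary graph with at least one edge
random_graph <- function(n, p = 0.3) {
  repeat {
    A <- matrix(0L, n, n)
    A[upper.tri(A)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
    A <- A + t(A)
    if (sum(A) > 0) return(A)
  }
}

# dense-grid minimizer of the EasyMKL gamma objective over the product of
# two probability simplices (compositions with resolution `step`)
simplex_grid <- function(k, step) {
  pts <- seq(0, 1, by = step)
  if (k == 2) {
    cbind(pts, 1 - pts)
  } else if (k == 3) {
    g <- expand.grid(a = pts, b = pts)
    g <- g[g$a + g$b <= 1 + 1e-12, ]
    cbind(g$a, g$b, pmax(1 - g$a - g$b, 0))
  } else stop("grid oracle supports 2 or 3 dimensions")
}

bf_easymkl_objective_min <- function(K, y, lam, step) {
  pos <- which(y > 0); neg <- which(y < 0)
  Gp <- simplex_grid(length(pos), step)
  Gn <- simplex_grid(length(neg), step)
  Q <- (y %o% y) * K
  best <- Inf
  for (i in seq_len(nrow(Gp))) {
    g <- numeric(length(y))
    g[pos] <- Gp[i, ]
    # vectorize over the negative-side grid
    G <- matrix(rep(g, nrow(Gn)), nrow = nrow(Gn), byrow = TRUE)
    G[, neg] <- Gn
    quad <- rowSums((G %*% Q) * G)
    obj <- (1 - lam) * quad + lam * rowSums(G^2)
    best <- min(best, min(obj))
  }
  best
}

# trapezoidal area under an ROC polygon (fpr/tpr sorted by threshold)
trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (utils::head(tpr[o], -1) + utils::tail(tpr[o], -1)) / 2)
}

# small cohort spec used across tests: two groups, light blocks
small_spec <- function(..., seed = 1L) {
  cohort_spec(group_sizes = c(AD = 20L, HC = 20L),
              block_sizes = c(m1 = 30L, m2 = 30L, APOE = 2L),
              seed = seed, ...)
}

# linearly separable two-cluster features with labels
toy_separable <- function(n_per = 10, sep = 4, p = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per * p, -sep / 2), n_per),
             matrix(stats::rnorm(n_per * p, sep / 2), n_per))
  list(X = X, y = rep(c(1, -1), each = n_per))
}

# normalized linear kernel on standardized features (PSD by construction)
toy_kernel <- function(X) {
  Z <- scale(X)
  Z[is.na(Z)] <- 0
  normalize_kernel(compute_kernel(Z, family = "linear") + diag(1e-9, nrow(Z)))
}
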