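#' Group connectivity matrix from features or time series
#'
#' Structural mode: Pearson correlation across subjects between every pair
#' of regional measures (one group's subjects x regions matrix).
#' Functional mode: per-subject Pearson correlation of regional time
#' series, Fisher-z averaged over subjects and transformed back.
#' In both modes negative correlations are set to zero and the diagonal is
#' zeroed, giving entries in \[0, 1\].
#'
#' @param x Structural: a subjects x regions matrix (>= 3 subjects).
#'   Functional: a list of regions x time matrices (T >= 20), one per
#'   subject.
#' @param source `"intersubject_structural"` or `"timeseries_functional"`.
#' @param group Optional group label recorded on the result.
#' @return A regions x regions matrix of class `connectivity_matrix` with
#'   attributes `source`, `group` and `n_zero_variance`.
#' @export
build_connectivity <- function(x, source = c("intersubject_structural",
                                             "timeseries_functional"),
                               group = NULL) {
  source <- match.arg(source)
  if (source == "intersubject_structural") {
    x <- as.matrix(x)
    if (nrow(x) < 3) stop("structural connectivity needs at least 3 subjects")
    sds <- apply(x, 2, stats::sd)
    C <- suppressWarnings(stats::cor(x))
  } else {
    if (!is.list(x)) stop("functional mode expects a list of region x time matrices")
    if (ncol(x[[1]]) < 20) stop("need at least 20 time points")
    zs <- lapply(x, function(ts) {
      Ci <- suppressWarnings(stats::cor(t(ts)))
      atanh(pmin(pmax(Ci, -1 + 1e-12), 1 - 1e-12))
    })
    Z <- Reduce(`+`, zs) / length(zs)
    C <- tanh(Z)
    sds <- apply(x[[1]], 1, stats::sd)  # zero-variance flagged from the data
    nz <- Reduce(`+`, lapply(x, function(ts) apply(ts, 1, stats::sd) == 0))
    sds[nz > 0] <- 0
  }
  n_zero <- sum(sds == 0)
  if (n_zero > 0) {
    warning(sprintf("%d zero-variance region(s); their correlations set to 0", n_zero))
  }
  C[!is.finite(C)] <- 0
  C[C < 0] <- 0
  diag(C) <- 0
  C <- (C + t(C)) / 2
  structure(C, class = c("connectivity_matrix", class(C)),
            source = source, group = group, n_zero_variance = n_zero)
}

# edge order of the upper triangle: weight descending, then smaller row,
# then smaller column index
.edge_order <- function(C) {
  n <- nrow(C)
  ut <- which(upper.tri(C))
  ij <- arrayInd(ut, dim(C))
  ord <- order(-C[ut], ij[, 1], ij[, 2])
  list(idx = ut[ord], ij = ij[ord, , drop = FALSE])
}

#' Binary undirected graph at a target density
#'
#' Keeps the `E = round(density * n(n-1)/2)` strongest edges (round half
#' up; ties broken by weight, then row, then column index) and binarizes.
#'
#' @param C A `connectivity_matrix` (or any symmetric non-negative matrix
#'   with zero diagonal).
#' @param density Target edge density in (0, 1).
#' @return A binary adjacency matrix of class `brain_graph` with attributes
#'   `density` (requested) and `n_edges`.
#' @export
threshold_by_density <- function(C, density) {
  if (density <= 0 || density >= 1) stop("'density' must lie in (0, 1)")
  n <- nrow(C)
  E <- round_half_up(density * n * (n - 1) / 2)
  if (E < 1) stop("requested density yields zero edges")
  eo <- .edge_order(C)
  keep <- eo$idx[seq_len(min(E, length(eo$idx)))]
  A <- matrix(0L, n, n, dimnames = dimnames(C))
  A[keep] <- 1L
  A <- A + t(A)
  structure(A, class = c("brain_graph", class(A)),
            density = density, n_edges = min(E, length(eo$idx)))
}

.as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(unclass(adj) * 1, mode = "undirected",
                                      diag = FALSE)
}

#' Nodal degree
#'
#' @param adj Binary adjacency matrix (`brain_graph`).
#' @return Integer degree per node.
#' @export
nodal_degree <- function(adj) {
  as.integer(rowSums(unclass(adj) > 0))
}

#' Modularity of a given partition
#'
#' `Q = sum_c (e_cc - a_c^2)` where `e_cc` is the fraction of edges inside
#' community c and `a_c` the fraction of edge endpoints in c. The trivial
#' one-community partition has Q = 0.
#'
#' @param adj Binary adjacency matrix.
#' @param membership Integer community label per node.
#' @return The modularity Q in \[-0.5, 1\].
#' @export
modularity_q <- function(adj, membership) {
  A <- unclass(adj) > 0
  m2 <- sum(A)  # twice the edge count
  if (m2 == 0) stop("graph has no edges")
  Q <- 0
  for (cc in unique(membership)) {
    in_c <- membership == cc
    e_cc <- sum(A[in_c, in_c]) / m2
    a_c <- sum(A[in_c, ]) / m2
    Q <- Q + e_cc - a_c^2
  }
  Q
}

# seeded Louvain-style maximization: best modularity over `restarts`
# vertex-permuted runs; falls back to one community if nothing beats Q = 0
.louvain_partition <- function(adj, seed = 1L, restarts = 10L) {
  g <- .as_igraph(adj)
  n <- nrow(adj)
  best_q <- -Inf; best_m <- rep(1L, n)
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      perm <- sample.int(n)
      gp <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(gp)
      memb <- integer(n)
      memb[perm] <- igraph::membership(cl)
      q <- modularity_q(adj, memb)
      if (q > best_q) { best_q <- q; best_m <- memb }
    }
  })
  if (best_q < 0) { best_q <- 0; best_m <- rep(1L, n) }
  list(membership = best_m, q = best_q)
}

#' Global graph metrics
#'
#' The four global summaries used for group network comparison:
#' \describe{
#'   \item{char_path_length}{Mean shortest-path length over ordered node
#'     pairs with finite distance; disconnected pairs are excluded and
#'     counted in `n_infinite_pairs`.}
#'   \item{local_efficiency_mean}{Mean over nodes of the local efficiency
#'     `1/(d_i (d_i - 1)) * sum over ordered neighbor pairs of the inverse
#'     shortest-path length inside the neighbor-induced subgraph`; 0 for
#'     nodes with degree < 2.}
#'   \item{transitivity}{Mean local clustering coefficient over all nodes
#'     (0 for degree < 2).}
#'   \item{modularity}{Q of the partition found by seeded Louvain
#'     maximization (best of `restarts`), or of `partition` if given.}
#' }
#'
#' @param adj Binary adjacency matrix (`brain_graph`) with at least one
#'   edge.
#' @param seed,restarts Controls for the Louvain search.
#' @param partition Optional fixed community labels for the modularity.
#' @return A list of class `global_metrics`.
#' @export
global_metrics <- function(adj, seed = 1L, restarts = 10L, partition = NULL) {
  A <- unclass(adj) > 0
  n <- nrow(A)
  if (sum(A) == 0) stop("graph has no edges")
  g <- .as_igraph(adj)
  D <- igraph::distances(g)
  offdiag <- D[row(D) != col(D)]
  finite <- is.finite(offdiag)
  lG <- mean(offdiag[finite])
  n_inf <- sum(!finite)
  deg <- rowSums(A)
  # local efficiency and local clustering per node
  le <- numeric(n); cc <- numeric(n)
  A2 <- A %*% A
  for (i in seq_len(n)) {
    if (deg[i] < 2) next
    nb <- which(A[i, ])
    t_i <- sum(A[nb, nb]) / 2          # triangles through i
    cc[i] <- 2 * t_i / (deg[i] * (deg[i] - 1))
    sub <- igraph::induced_subgraph(g, nb)
    Ds <- igraph::distances(sub)
    inv <- 1 / Ds[row(Ds) != col(Ds)]
    inv[!is.finite(inv)] <- 0
    le[i] <- sum(inv) / (deg[i] * (deg[i] - 1))
  }
  part <- if (is.null(partition)) .louvain_partition(adj, seed, restarts)
          else list(membership = partition, q = modularity_q(adj, partition))
  structure(list(char_path_length = lG, n_infinite_pairs = n_inf,
                 local_efficiency = le, local_efficiency_mean = mean(le),
                 transitivity = mean(cc), modularity = part$q,
                 partition = part$membership, degree = as.integer(deg)),
            class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf("l_G = %.4f (%d infinite pairs excluded), LE = %.4f, T = %.4f, Q = %.4f\n",
              x$char_path_length, x$n_infinite_pairs,
              x$local_efficiency_mean, x$transitivity, x$modularity))
  invisible(x)
}

.metric_value <- function(adj, measure, seed = 1L) {
  switch(measure,
         char_path_length = {
           g <- .as_igraph(adj)
           D <- igraph::distances(g)
           off <- D[row(D) != col(D)]
           mean(off[is.finite(off)])
         },
         transitivity = {
           A <- unclass(adj) > 0
           deg <- rowSums(A)
           cc <- numeric(nrow(A))
           for (i in which(deg >= 2)) {
             nb <- which(A[i, ])
             cc[i] <- sum(A[nb, nb]) / (deg[i] * (deg[i] - 1))
           }
           mean(cc)
         },
         local_efficiency = global_metrics(adj, seed = seed)$local_efficiency_mean,
         modularity = .louvain_partition(adj, seed = seed)$q,
         stop(sprintf("unknown measure '%s'", measure)))
}

#' Permutation test for group differences in a graph measure
#'
#' For every density in the sweep, the observed difference
#' `measure(group A) - measure(group B)` between the groups' connectivity
#' graphs is compared with a permutation null built by pooling the subjects,
#' reassigning group labels at random, and recomputing both networks and
#' the measure. Two-tailed p-values use the add-one estimator
#' `(1 + #{|null| >= |obs|}) / (n_perm + 1)`; the 95% interval is the
#' 2.5/97.5 percentile band of the null.
#'
#' @param group_a,group_b Subjects x regions matrices (structural source;
#'   subjects are the exchangeable units). At least 3 subjects each.
#' @param measure One of `"transitivity"`, `"char_path_length"`,
#'   `"local_efficiency"`, `"modularity"`.
#' @param densities Density sweep (default 5-25% in 0.5% steps).
#' @param n_perm Number of permutations (default 1000; below 100 a warning
#'   is issued).
#' @param alpha Significance level for the flags (default 0.05).
#' @param seed Integer seed.
#' @return An object of class `permutation_result`: data.frame `table` with
#'   density, observed difference, p, CI bounds and significance flag, the
#'   null matrix, and the count of re-sampled failed permutations.
#' @export
permutation_group_test <- function(group_a, group_b,
                                   measure = c("transitivity",
                                               "char_path_length",
                                               "local_efficiency",
                                               "modularity"),
                                   densities = seq(0.05, 0.25, by = 0.005),
                                   n_perm = 1000L, alpha = 0.05, seed = 1L) {
  measure <- match.arg(measure)
  if (n_perm < 100) warning("fewer than 100 permutations gives a coarse p-value")
  na <- nrow(group_a); nb <- nrow(group_b)
  if (na < 3 || nb < 3) stop("need at least 3 subjects per group")
  pooled <- rbind(group_a, group_b)
  measure_at <- function(rows_a, rows_b) {
    Ca <- suppressWarnings(build_connectivity(pooled[rows_a, , drop = FALSE]))
    Cb <- suppressWarnings(build_connectivity(pooled[rows_b, , drop = FALSE]))
    vapply(densities, function(d) {
      .metric_value(threshold_by_density(Ca, d), measure, seed = seed) -
        .metric_value(threshold_by_density(Cb, d), measure, seed = seed)
    }, 0)
  }
  obs <- measure_at(seq_len(na), na + seq_len(nb))
  null <- matrix(NA_real_, n_perm, length(densities))
  n_failed <- 0L
  with_seed(seed, {
    p <- 1L
    while (p <= n_perm) {
      idx <- sample.int(na + nb)
      val <- tryCatch(measure_at(idx[seq_len(na)], idx[na + seq_len(nb)]),
                      error = function(e) NULL)
      if (is.null(val)) { n_failed <- n_failed + 1L; next }
      null[p, ] <- val
      p <- p + 1L
    }
  })
  pval <- vapply(seq_along(densities), function(j) {
    (1 + sum(abs(null[, j]) >= abs(obs[j]))) / (n_perm + 1)
  }, 0)
  ci <- apply(null, 2, stats::quantile, probs = c(0.025, 0.975))
  tab <- data.frame(density = densities, observed = obs, p = pval,
                    ci_low = ci[1, ], ci_high = ci[2, ],
                    significant = pval < alpha)
  structure(list(table = tab, measure = measure, null = null,
                 n_perm = n_perm, n_failed_permutations = n_failed,
                 alpha = alpha),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %d permutations): %d/%d densities significant at %.2f\n",
              x$measure, x$n_perm, sum(x$table$significant),
              nrow(x$table), x$alpha))
  invisible(x)
}

#' @export
plot.permutation_result <- function(x, ...) {
  tab <- x$table
  rng <- range(c(tab$observed, tab$ci_low, tab$ci_high))
  graphics::plot(tab$density, tab$observed, type = "b", pch = 16,
                 ylim = rng, xlab = "Network density",
                 ylab = sprintf("Difference in %s", x$measure), ...)
  graphics::lines(tab$density, tab$ci_low, lty = 2, col = "darkred")
  graphics::lines(tab$density, tab$ci_high, lty = 2, col = "darkred")
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up false discovery rate control over a vector of p-values (e.g.
#' nodal-degree comparisons across regions).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level for the flags (default 0.05).
#' @return A list with `adjusted` and logical `significant`.
#' @export
fdr_adjust <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) return(list(adjusted = numeric(0), significant = logical(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, significant = adj <= alpha)
}
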