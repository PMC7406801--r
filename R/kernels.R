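#' Feature standardization statistics
#'
#' Per-feature mean and SD computed on training data, used to z-score both
#' training and test blocks so that no test-set information leaks into the
#' kernels. Constant features get scale 1 (they become exactly zero).
#'
#' @param X Training feature matrix (subjects x features).
#' @return A list with `center` and `scale` vectors.
#' @export
standardization_stats <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

#' Apply standardization statistics to a feature block
#'
#' @param X Feature matrix.
#' @param stats A list from [standardization_stats()].
#' @return The z-scored matrix.
#' @export
apply_standardization <- function(X, stats) {
  sweep(sweep(X, 2, stats$center), 2, stats$scale, "/")
}

#' Compute a base kernel matrix
#'
#' Polynomial `k(x, y) = (x'y + c)^d`, Gaussian RBF
#' `k(x, y) = exp(-gamma ||x - y||^2)` (with `gamma = 1 / (2 sigma^2)`), or
#' linear `k(x, y) = x'y`. With `Y = NULL` the symmetric training kernel is
#' returned; otherwise the `nrow(X) x nrow(Y)` cross kernel.
#'
#' @param X Feature matrix (rows are samples); standardize first.
#' @param Y Optional second matrix for cross kernels (e.g. test vs train).
#' @param family `"polynomial"`, `"rbf"` or `"linear"`.
#' @param degree Polynomial degree d (positive integer).
#' @param offset Polynomial offset c (>= 0).
#' @param gamma RBF width gamma (> 0; default `1 / ncol(X)`).
#' @param modality Optional name recorded on the result.
#' @return A kernel matrix with attributes `family`, `params`, `modality`.
#' @export
compute_kernel <- function(X, Y = NULL, family = c("polynomial", "rbf", "linear"),
                           degree = 2L, offset = 1, gamma = NULL,
                           modality = NULL) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (anyNA(X) || (!is.null(Y) && anyNA(Y))) stop("features must have no missing values")
  Yg <- if (is.null(Y)) X else as.matrix(Y)
  K <- switch(family,
    linear = tcrossprod(X, Yg),
    polynomial = {
      if (degree < 1 || degree != round(degree)) {
        stop("'degree' must be a positive integer")
      }
      (tcrossprod(X, Yg) + offset)^degree
    },
    rbf = {
      if (is.null(gamma)) gamma <- 1 / ncol(X)
      if (gamma <= 0) stop("'gamma' must be positive")
      d2 <- outer(rowSums(X^2), rowSums(Yg^2), "+") - 2 * tcrossprod(X, Yg)
      exp(-gamma * pmax(d2, 0))
    })
  attr(K, "family") <- family
  attr(K, "params") <- switch(family,
                              polynomial = list(degree = degree, offset = offset),
                              rbf = list(gamma = gamma),
                              linear = list())
  attr(K, "modality") <- modality
  K
}

#' Cosine (unit-diagonal) kernel normalization
#'
#' `K'(x, y) = K(x, y) / sqrt(K(x, x) K(y, y))`, which forces unit
#' self-similarity (diagonal exactly 1, trace n) and preserves positive
#' semidefiniteness. For cross kernels, pass the training and test
#' self-similarities explicitly.
#'
#' @param K Kernel matrix (symmetric, or a test x train cross kernel).
#' @param diag_x,diag_y Self-similarities `k(x, x)` for the rows/columns;
#'   defaults to `diag(K)` for the symmetric case.
#' @return The normalized kernel, attributes preserved.
#' @export
normalize_kernel <- function(K, diag_x = NULL, diag_y = NULL) {
  if (is.null(diag_x) && is.null(diag_y)) {
    diag_x <- diag_y <- diag(K)
  }
  bad <- which(c(diag_x, diag_y) <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive self-similarity for subject %d; cannot normalize", bad[1]))
  }
  out <- K / sqrt(outer(diag_x, diag_y))
  attributes(out)[c("family", "params", "modality")] <-
    attributes(K)[c("family", "params", "modality")]
  out
}

#' Convex combination of kernels
#'
#' `K = sum_m w_m K_m` with non-negative weights summing to 1; a convex
#' combination of PSD matrices is PSD.
#'
#' @param kernels List of kernel matrices over the same subjects.
#' @param weights Non-negative weights (default uniform); must sum to 1
#'   within 1e-8.
#' @return The fused kernel matrix.
#' @export
combine_kernels <- function(kernels, weights = NULL) {
  R <- length(kernels)
  if (!R) stop("'kernels' must be non-empty")
  dims <- vapply(kernels, function(K) dim(K), integer(2))
  if (any(dims != dims[, 1])) stop("all kernels must share one dimension")
  if (is.null(weights)) weights <- rep(1 / R, R)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1")
  }
  K <- matrix(0, dims[1, 1], dims[2, 1])
  for (r in seq_len(R)) K <- K + weights[r] * kernels[[r]]
  K
}

#' Per-modality normalized kernels for train (and optionally test) subjects
#'
#' For every modality block: z-score using training statistics, compute the
#' base kernel, and cosine-normalize. Returns the train kernels, the
#' test x train cross kernels, and the fusion weights (uniform by default,
#' matching the convex-combination contract).
#'
#' @param cohort A `multimodal_cohort`.
#' @param train,test Integer subject indices (e.g. from [split_cohort()]);
#'   `test = NULL` kernelizes the whole of `train` only.
#' @param modalities Blocks to use (default all).
#' @param family,degree,offset,gamma Passed to [compute_kernel()].
#' @param weights Prior fusion weights (default uniform over modalities).
#' @return A list of class `kernel_set`: `train` (named list of kernels),
#'   `cross` (named list, or NULL), `weights`, `modalities`, `stats`.
#' @export
build_kernel_set <- function(cohort, train, test = NULL,
                             modalities = names(cohort$blocks),
                             family = "polynomial", degree = 2L, offset = 1,
                             gamma = NULL, weights = NULL) {
  Ktr <- list(); Kcr <- if (is.null(test)) NULL else list()
  stats_list <- list()
  for (m in modalities) {
    Xtr <- cohort$blocks[[m]][train, , drop = FALSE]
    st <- standardization_stats(Xtr)
    Z <- apply_standardization(Xtr, st)
    K <- compute_kernel(Z, family = family, degree = degree, offset = offset,
                        gamma = gamma, modality = m)
    dtr <- diag(K)
    Ktr[[m]] <- normalize_kernel(K)
    if (!is.null(test)) {
      Zte <- apply_standardization(cohort$blocks[[m]][test, , drop = FALSE], st)
      Kc <- compute_kernel(Zte, Z, family = family, degree = degree,
                           offset = offset, gamma = gamma, modality = m)
      dte <- diag(compute_kernel(Zte, family = family, degree = degree,
                                 offset = offset, gamma = gamma))
      Kcr[[m]] <- normalize_kernel(Kc, diag_x = dte, diag_y = dtr)
    }
    stats_list[[m]] <- st
  }
  if (is.null(weights)) weights <- rep(1 / length(modalities), length(modalities))
  structure(list(train = Ktr, cross = Kcr, weights = weights,
                 modalities = modalities, stats = stats_list,
                 params = list(family = family, degree = degree,
                               offset = offset, gamma = gamma)),
            class = "kernel_set")
}
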