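# ---- gamma subproblem -------------------------------------------------------
# minimize (1 - lam) * g' Q g + lam * ||g||^2 over the product of the
# positive- and negative-class probability simplices, by projected gradient
# with a fixed 1/L step (L from the largest eigenvalue of the quadratic),
# deterministic uniform initialization.
.solve_gamma <- function(Q, y, lam, tol = 1e-7, maxit = 10000L) {
  n <- length(y)
  pos <- which(y > 0); neg <- which(y < 0)
  g <- numeric(n)
  g[pos] <- 1 / length(pos); g[neg] <- 1 / length(neg)
  obj <- function(g) (1 - lam) * drop(crossprod(g, Q %*% g)) + lam * sum(g^2)
  ev <- tryCatch(eigen(Q, symmetric = TRUE, only.values = TRUE)$values[1],
                 error = function(e) sum(abs(Q)) / nrow(Q))
  L <- 2 * ((1 - lam) * max(ev, 0) + lam)
  if (L <= 0) L <- 1
  step <- 1 / L
  f_old <- obj(g)
  for (it in seq_len(maxit)) {
    grad <- 2 * (1 - lam) * (Q %*% g) + 2 * lam * g
    g_new <- g - step * drop(grad)
    g_new[pos] <- project_simplex(g_new[pos])
    g_new[neg] <- project_simplex(g_new[neg])
    f_new <- obj(g_new)
    g <- g_new
    if (abs(f_old - f_new) <= tol) { f_old <- f_new; break }
    f_old <- f_new
  }
  list(gamma = g, objective = f_old, iterations = it)
}

.easymkl_objective <- function(K, y, gamma, lam) {
  yg <- y * gamma
  (1 - lam) * drop(crossprod(yg, K %*% yg)) + lam * sum(gamma^2)
}

.check_psd <- function(K, tol_scale = 1e-6) {
  ev <- eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol_scale * max(abs(ev), 1)) {
    stop("kernel matrix is not positive semidefinite within tolerance")
  }
}

.coerce_labels <- function(y, positive = NULL) {
  if (is.factor(y) || is.character(y)) {
    y <- as.factor(y)
    lev <- levels(droplevels(y))
    if (length(lev) != 2) stop("exactly two classes are required")
    if (is.null(positive)) positive <- lev[1]
    if (!positive %in% lev) stop("'positive' is not a level of y")
    num <- ifelse(y == positive, 1, -1)
    list(y = num, positive = positive,
         negative = setdiff(lev, positive))
  } else {
    if (!all(y %in% c(-1, 1))) stop("numeric labels must be +1/-1")
    list(y = as.numeric(y), positive = "+1", negative = "-1")
  }
}

#' Fit an EasyMKL multiple kernel classifier
#'
#' EasyMKL learns a convex-hull maximum-margin classifier together with
#' kernel combination weights by solving, for a fixed regularizer
#' `lambda` in \[0, 1\], a quadratic problem over the product of the
#' positive- and negative-class probability simplices (the domain Gamma).
#' The published two-phase reduction is used: (1) solve the gamma problem on
#' the prior-weighted sum kernel; (2) set the kernel weights
#' `eta_r` proportional to the margin contribution
#' `gamma' diag(y) K_r diag(y) gamma` of each base kernel (normalized to
#' unit Euclidean norm), rebuild the fused kernel
#' `K* = sum_r eta_r w_r K_r`, and re-solve gamma once on `K*`. The decision
#' threshold places the boundary midway between the two class scores.
#'
#' @param kernels Either a `kernel_set` from [build_kernel_set()] or a list
#'   of (normalized, PSD) training kernel matrices.
#' @param y Class labels: a two-level factor/character vector, or +1/-1.
#' @param lam Regularizer lambda in \[0, 1\]; `NULL` selects it by
#'   leave-one-out cross-validation over `lam_grid`.
#' @param lam_grid Grid searched when `lam = NULL` (default 0, 0.1, ..., 1).
#' @param weights Prior fusion weights w_m (default: the kernel set's, else
#'   uniform); these multiply the learned eta.
#' @param positive Label treated as the positive (disease) class; defaults
#'   to the first factor level.
#' @param tol,maxit Projected-gradient stopping controls.
#' @param check_psd Verify each kernel's positive semidefiniteness (skipped
#'   internally during cross-validation, where submatrices of checked
#'   kernels are refitted).
#' @return An object of class `easymkl` with components `gamma`
#'   (coefficients over training subjects; each class block sums to 1),
#'   `eta` (kernel weights, unit L2 norm), `lam`, `bias`, `weights`,
#'   `y` (+1/-1 training labels), `K_star` (fused training kernel),
#'   `objective` (per phase), `cv` (LOOCV table when lambda was selected).
#' @references Aiolli, F. and Donini, M. (2015). EasyMKL: a scalable
#'   multiple kernel learning algorithm. Neurocomputing 169, 215-224.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(40, -1), 20), matrix(rnorm(40, 1), 20))
#' y <- rep(c("case", "control"), each = 20)
#' K <- normalize_kernel(compute_kernel(scale(X), family = "linear") + diag(1e-8, 40))
#' fit <- easymkl(list(K), y, lam = 0.2)
#' predict(fit, list(K[1:5, ]))
#' @export
easymkl <- function(kernels, y, lam = 0.1, lam_grid = seq(0, 1, by = 0.1),
                    weights = NULL, positive = NULL, tol = 1e-7,
                    maxit = 10000L, check_psd = TRUE) {
  ks <- NULL
  if (inherits(kernels, "kernel_set")) {
    ks <- kernels
    if (is.null(weights)) weights <- ks$weights
    kernels <- ks$train
  }
  R <- length(kernels)
  if (is.null(weights)) weights <- rep(1 / R, R)
  if (length(weights) != R || any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("'weights' must be non-negative and sum to 1")
  }
  lab <- .coerce_labels(y, positive)
  yy <- lab$y
  if (!any(yy > 0) || !any(yy < 0)) stop("both classes must be present")
  n <- length(yy)
  if (!all(vapply(kernels, function(K) all(dim(K) == n), TRUE))) {
    stop("kernel dimensions must match the number of labels")
  }
  if (check_psd) for (K in kernels) .check_psd(K)
  cv <- NULL
  if (is.null(lam)) {
    sel <- select_lambda_loocv(kernels, y, lam_grid = lam_grid,
                               weights = weights, positive = lab$positive)
    lam <- sel$best_lambda
    cv <- sel$table
  }
  if (lam < 0 || lam > 1) stop("'lam' must lie in [0, 1]")
  K_sum <- combine_kernels(kernels, weights)
  s1 <- .solve_gamma(yy * t(yy * K_sum), yy, lam, tol, maxit)
  yg <- yy * s1$gamma
  eta <- vapply(kernels, function(K) drop(crossprod(yg, K %*% yg)), 0)
  eta <- pmax(eta, 0)
  if (sum(eta^2) == 0) eta <- rep(1, R)
  eta <- eta / sqrt(sum(eta^2))
  K_star <- matrix(0, n, n)
  for (r in seq_len(R)) K_star <- K_star + eta[r] * weights[r] * kernels[[r]]
  s2 <- .solve_gamma(yy * t(yy * K_star), yy, lam, tol, maxit)
  gamma <- s2$gamma
  yg <- yy * gamma
  s_pos <- drop(crossprod(yg, K_star %*% (gamma * (yy > 0))))
  s_neg <- drop(crossprod(yg, K_star %*% (gamma * (yy < 0))))
  bias <- -0.5 * (s_pos + s_neg)
  names(eta) <- names(kernels) %||% paste0("K", seq_len(R))
  out <- list(gamma = gamma, eta = eta, lam = lam, bias = bias,
              weights = weights, y = yy, positive = lab$positive,
              negative = lab$negative, K_star = K_star,
              objective = c(phase1 = .easymkl_objective(K_star, yy, s1$gamma, lam),
                            final = s2$objective),
              iterations = c(s1$iterations, s2$iterations),
              kernel_set = ks, cv = cv, n = n, call = match.call())
  class(out) <- "easymkl"
  out
}

#' Predict from an EasyMKL fit
#'
#' The decision score of a test sample s is
#' `sum_i gamma_i y_i K*(x_i, s) + bias`, with `K*` the learned fused
#' kernel; the label is its sign (a score of exactly 0 is assigned to the
#' positive class).
#'
#' @param object An `easymkl` fit.
#' @param cross_kernels List of test x train kernel blocks, one per base
#'   kernel, in the training order (or a `kernel_set` carrying `cross`).
#' @param type `"class"` for labels, `"score"` for the decision values.
#' @param ... Unused.
#' @return Labels (in the original coding) or numeric scores.
#' @export
predict.easymkl <- function(object, cross_kernels = NULL,
                            type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.null(cross_kernels)) cross_kernels <- object$kernel_set
  if (inherits(cross_kernels, "kernel_set")) cross_kernels <- cross_kernels$cross
  if (is.null(cross_kernels)) stop("'cross_kernels' is required")
  if (is.matrix(cross_kernels)) cross_kernels <- list(cross_kernels)
  R <- length(object$eta)
  if (length(cross_kernels) != R) stop("expected one cross kernel per base kernel")
  if (ncol(cross_kernels[[1]]) != object$n) {
    stop("cross kernels must have one column per training subject")
  }
  Kc <- matrix(0, nrow(cross_kernels[[1]]), object$n)
  for (r in seq_len(R)) {
    Kc <- Kc + object$eta[r] * object$weights[r] * cross_kernels[[r]]
  }
  score <- drop(Kc %*% (object$gamma * object$y)) + object$bias
  if (type == "score") return(score)
  lab <- ifelse(score >= 0, object$positive, object$negative)
  if (object$positive == "+1") as.numeric(lab) else lab
}

#' @export
print.easymkl <- function(x, ...) {
  cat(sprintf("EasyMKL fit: %d training subjects, %d kernels, lambda = %.3g\n",
              x$n, length(x$eta), x$lam))
  cat("kernel weights (eta):\n")
  print(round(x$eta, 4))
  invisible(x)
}

#' @export
summary.easymkl <- function(object, ...) {
  fitted_scores <- drop(object$K_star %*% (object$gamma * object$y)) + object$bias
  train_acc <- mean((fitted_scores >= 0) == (object$y > 0))
  structure(list(fit = object, train_accuracy = train_acc,
                 class_sizes = c(positive = sum(object$y > 0),
                                 negative = sum(object$y < 0))),
            class = "summary.easymkl")
}

#' @export
print.summary.easymkl <- function(x, ...) {
  print(x$fit)
  cat(sprintf("classes: %s = %d, %s = %d; training accuracy %.3f\n",
              x$fit$positive, x$class_sizes[1], x$fit$negative,
              x$class_sizes[2], x$train_accuracy))
  if (!is.null(x$fit$cv)) {
    cat("LOOCV lambda selection:\n"); print(x$fit$cv)
  }
  invisible(x)
}

#' @export
coef.easymkl <- function(object, ...) {
  list(eta = object$eta, gamma = object$gamma, bias = object$bias,
       lam = object$lam)
}

#' @export
fitted.easymkl <- function(object, ...) {
  drop(object$K_star %*% (object$gamma * object$y)) + object$bias
}

#' Select the EasyMKL regularizer by leave-one-out cross-validation
#'
#' For every lambda in the grid, each training subject is held out in turn,
#' the classifier is refitted on the remaining kernel rows/columns, and the
#' held-out subject is scored; the lambda with the highest LOOCV accuracy is
#' returned (ties go to the smallest lambda).
#'
#' @param kernels List of training kernel matrices (or a `kernel_set`).
#' @param y Labels (two-level factor or +1/-1), at least 3 per class.
#' @param lam_grid Candidate lambdas in \[0, 1\].
#' @param weights Prior fusion weights.
#' @param positive Positive-class label.
#' @return A list with `best_lambda` and `table` (lambda, loocv_accuracy).
#' @export
select_lambda_loocv <- function(kernels, y, lam_grid = seq(0, 1, by = 0.1),
                                weights = NULL, positive = NULL) {
  if (inherits(kernels, "kernel_set")) kernels <- kernels$train
  if (!length(lam_grid)) stop("'lam_grid' must be non-empty")
  lam_grid <- sort(lam_grid)  # ties resolve to the smallest lambda
  lab <- .coerce_labels(y, positive)
  yy <- lab$y
  if (sum(yy > 0) < 3 || sum(yy < 0) < 3) stop("need at least 3 subjects per class")
  n <- length(yy)
  acc <- numeric(length(lam_grid))
  for (li in seq_along(lam_grid)) {
    correct <- logical(n)
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      Ktr <- lapply(kernels, function(K) K[tr, tr, drop = FALSE])
      fit <- easymkl(Ktr, yy[tr], lam = lam_grid[li], weights = weights,
                     check_psd = FALSE)
      Kcr <- lapply(kernels, function(K) K[i, tr, drop = FALSE])
      correct[i] <- predict(fit, Kcr) * yy[i] > 0
    }
    acc[li] <- mean(correct)
  }
  best <- lam_grid[which.max(acc)]  # which.max takes the first (smallest) tie
  list(best_lambda = best,
       table = data.frame(lambda = lam_grid, loocv_accuracy = acc))
}
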