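test_that("lambda = 1 gives the closed-form uniform gamma", {
  toy <- toy_separable(6, seed = 1)
  K <- toy_kernel(toy$X)
  fit <- easymkl(list(K), toy$y, lam = 1)
  expect_equal(fit$gamma[toy$y > 0], rep(1 / 6, 6), tolerance = 1e-8)
  expect_equal(fit$gamma[toy$y < 0], rep(1 / 6, 6), tolerance = 1e-8)
})

test_that("gamma lies in the product of class simplices", {
  toy <- toy_separable(8, sep = 1, seed = 2)
  K <- toy_kernel(toy$X)
  for (lam in c(0, 0.3, 0.7)) {
    fit <- easymkl(list(K), toy$y, lam = lam)
    expect_true(all(fit$gamma >= -1e-12))
    expect_equal(sum(fit$gamma[toy$y > 0]), 1, tolerance = 1e-8)
    expect_equal(sum(fit$gamma[toy$y < 0]), 1, tolerance = 1e-8)
    expect_equal(sum(fit$eta^2), 1, tolerance = 1e-8)
  }
})

test_that("identical kernels share the weight symmetrically", {
  toy <- toy_separable(5, seed = 3)
  K <- toy_kernel(toy$X)
  fit <- easymkl(list(a = K, b = K), toy$y, lam = 0.4)
  expect_equal(unname(fit$eta), rep(1 / sqrt(2), 2), tolerance = 1e-9)
})

test_that("solver attains the brute-force optimum on tiny problems", {
  set.seed(4)
  for (rep in 1:3) {
    X <- matrix(stats::rnorm(8), 4, 2)
    y <- c(1, 1, -1, -1)
    K <- toy_kernel(X)
    for (lam in c(0.2, 0.8)) {
      fit <- easymkl(list(K), y, lam = lam)
      grid_min <- bf_easymkl_objective_min(fit$K_star, y, lam, step = 0.005)
      expect_lt(abs(fit$objective["final"] - grid_min), 1e-3)
    }
  }
})

test_that("the re-solve never increases the objective on the fused kernel", {
  set.seed(5)
  for (rep in 1:5) {
    X <- matrix(stats::rnorm(40), 10, 4)
    y <- rep(c(1, -1), each = 5)
    K1 <- toy_kernel(X); K2 <- toy_kernel(X + stats::rnorm(40))
    fit <- easymkl(list(K1, K2), y, lam = 0.3)
    expect_lte(fit$objective["final"], fit$objective["phase1"] + 1e-10)
  }
})

test_that("single-kernel fit degenerates to eta = 1 and classifies the toy perfectly", {
  toy <- toy_separable(8, sep = 5, seed = 6)
  K <- toy_kernel(toy$X)
  fit <- easymkl(list(K), toy$y, lam = 0.2)
  expect_equal(unname(fit$eta), 1)
  # train = test: perfect separation
  pred <- predict(fit, list(K))
  expect_equal(pred, toy$y)
  # duplicated training point keeps its label
  expect_equal(predict(fit, list(K[3, , drop = FALSE])), toy$y[3])
})

test_that("the bias centers symmetric two-cluster data", {
  # perfectly symmetric noise-free clusters: the class-barycenter midpoint
  # (the origin) must score ~0
  X <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)) * 2
  X <- rbind(X + 5, X - 5)
  y <- rep(c(1, -1), each = 4)
  Z <- scale(X, scale = FALSE)
  K <- compute_kernel(Z, family = "linear") + diag(1e-12, 8)
  fit <- easymkl(list(K), y, lam = 0.5)
  Kc <- compute_kernel(matrix(0, 1, 2), Z, family = "linear")
  expect_lt(abs(predict(fit, list(Kc), type = "score")), 1e-6)
})

test_that("informative kernels outrank pure-noise kernels", {
  wins <- 0L
  for (s in 1:10) {
    toy <- toy_separable(10, sep = 3, seed = 100 + s)
    set.seed(200 + s)
    noise <- matrix(stats::rnorm(length(toy$X)), nrow(toy$X))
    fit <- easymkl(list(info = toy_kernel(toy$X), noise = toy_kernel(noise)),
                   toy$y, lam = 0.2)
    if (fit$eta["info"] > fit$eta["noise"]) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("LOOCV lambda selection: separable reaches 1, singleton grid returned", {
  toy <- toy_separable(6, sep = 6, seed = 7)
  K <- toy_kernel(toy$X)
  sel <- select_lambda_loocv(list(K), toy$y, lam_grid = c(0, 0.5, 1))
  expect_equal(max(sel$table$loocv_accuracy), 1)
  expect_equal(select_lambda_loocv(list(K), toy$y, lam_grid = 0.5)$best_lambda, 0.5)
  expect_error(select_lambda_loocv(list(K), toy$y, lam_grid = numeric(0)),
               "non-empty")
})

test_that("label-shuffled LOOCV accuracy sits at chance level", {
  accs <- numeric(20)
  for (s in 1:20) {
    toy <- toy_separable(6, sep = 4, seed = 300 + s)
    set.seed(400 + s)
    y_shuf <- sample(toy$y)
    K <- toy_kernel(toy$X)
    sel <- select_lambda_loocv(list(K), y_shuf, lam_grid = c(0, 0.5, 1))
    accs[s] <- max(sel$table$loocv_accuracy)
  }
  expect_gte(mean(accs), 0.3)
  expect_lte(mean(accs), 0.8)  # max over the grid biases slightly upward
})

test_that("training output ignores test data entirely", {
  co <- generate_cohort(small_spec(seed = 31))
  sp <- suppressWarnings(split_cohort(co, seed = 1))
  ks <- build_kernel_set(co, sp$train, sp$test)
  f1 <- easymkl(ks, co$labels[sp$train], lam = 0.3, positive = "AD")
  ks2 <- ks
  ks2$cross <- lapply(ks2$cross, function(K) K * 0)
  f2 <- easymkl(ks2, co$labels[sp$train], lam = 0.3, positive = "AD")
  expect_equal(f1$gamma, f2$gamma)
  expect_equal(f1$eta, f2$eta)
  expect_equal(f1$bias, f2$bias)
})

test_that("degenerate inputs are rejected", {
  toy <- toy_separable(4, seed = 8)
  K <- toy_kernel(toy$X)
  expect_error(easymkl(list(K), rep(1, 8), lam = 0.5), "both classes")
  expect_error(easymkl(list(K), toy$y, lam = 1.5), "\\[0, 1\\]")
  expect_error(easymkl(list(K - 0.5 * diag(8)), toy$y, lam = 0.5),
               "positive semidefinite")
  expect_error(predict(easymkl(list(K), toy$y, lam = 0.5),
                       list(K[, 1:3])), "training subject")
})

test_that("RBF-SVM grid baseline separates the toy and breaks ties downward", {
  toy <- toy_separable(10, sep = 5, seed = 9)
  Z <- scale(toy$X)
  fit <- fit_svm_rbf_grid(Z, factor(toy$y), seed = 1)
  expect_equal(as.numeric(as.character(predict(fit, Z))), toy$y)
  expect_true(fit$C %in% 1:9 && fit$gamma %in% c(1e-4, 1e-3, 1e-2, 1e-1, 1, 7))
  # a duplicated training point keeps its label
  expect_equal(as.numeric(as.character(predict(fit, Z[1, , drop = FALSE]))),
               toy$y[1])
  # ties on a perfectly separable toy resolve to the smallest C
  best_acc <- max(fit$cv_table$accuracy)
  cands <- fit$cv_table[fit$cv_table$accuracy == best_acc, ]
  expect_equal(fit$C, min(cands$C))
})
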