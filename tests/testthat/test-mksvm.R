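# Independent dual-QP oracle via kernlab's interior-point solver:
# min 0.5 a' Q a - e' a  s.t.  y' a = 0,  0 <= a <= C
ipop_dual <- function(K, y, C) {
  n <- length(y)
  Q <- K * tcrossprod(y)
  res <- kernlab::ipop(c = rep(-1, n), H = Q + diag(1e-10, n),
                       A = matrix(y, 1), b = 0, r = 0,
                       l = rep(0, n), u = rep(C, n), sigf = 9)
  kernlab::primal(res)
}

dual_objective <- function(alpha, K, y) {
  sum(alpha) - 0.5 * drop(t(alpha * y) %*% K %*% (alpha * y))
}

# Largest violation of the Karush-Kuhn-Tucker conditions of a fitted model
kkt_residual <- function(model, K) {
  f <- drop(K %*% (model$alpha * model$y)) + model$b
  yf <- model$y * f
  viol <- numeric(length(yf))
  free <- model$alpha > 1e-8 & model$alpha < model$C - 1e-8
  at_zero <- model$alpha <= 1e-8
  at_C <- model$alpha >= model$C - 1e-8
  viol[free] <- abs(yf[free] - 1)
  viol[at_zero] <- pmax(0, 1 - yf[at_zero])
  viol[at_C] <- pmax(0, yf[at_C] - 1)
  max(viol)
}

test_that("a one-feature kernel reproduces the inner-product Gram", {
  x <- matrix(c(1, -1), ncol = 1)
  kb <- build_kernel(x)
  expect_equal(kb$train, matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
  expect_equal(kb$normalizer, 1)
})

test_that("duplicated subjects give identical Gram rows", {
  set.seed(3)
  x <- matrix(rnorm(12), 4, 3)
  x[2, ] <- x[1, ]
  kb <- build_kernel(x)
  expect_equal(kb$train[1, ], kb$train[2, ])
})

test_that("Gram matrices are positive semidefinite", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- matrix(rnorm(15 * 8), 15, 8)
    kb <- build_kernel(x)
    expect_gte(min(eigen(kb$train, symmetric = TRUE)$values), -1e-8)
  }
})

test_that("kernel combination respects simplex vertices and convexity", {
  set.seed(7)
  x1 <- matrix(rnorm(20), 5, 4)
  x2 <- matrix(rnorm(10), 5, 2)
  k1 <- build_kernel(x1)$train
  k2 <- build_kernel(x2)$train
  expect_equal(combine_kernels(list(k1, k2), c(1, 0)), k1)
  expect_equal(combine_kernels(list(k1, k1), c(0.3, 0.7)), k1)
  mixed <- combine_kernels(list(k1, k2), c(0.5, 0.5))
  expect_gte(min(eigen(mixed, symmetric = TRUE)$values), -1e-8)
  expect_error(combine_kernels(list(k1, k2), c(0.5, 0.6)), "sum to 1")
  expect_error(combine_kernels(list(k1, k2[1:4, 1:4]), c(0.5, 0.5)),
               "conformable")
})

test_that("the two-point problem recovers the hand KKT solution", {
  # points x = +1 (y = +1) and x = -1 (y = -1), linear kernel, C = 10:
  # alpha = (0.5, 0.5), b = 0, f(x) = x
  K <- matrix(c(1, -1, -1, 1), 2)
  model <- svm_fit(K, c(1, -1), C = 10)
  expect_equal(model$alpha, c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(model$b, 0, tolerance = 1e-8)
  pred <- svm_decide(model, matrix(c(0.2, -0.2), 1))
  expect_equal(pred$decision, 0.2, tolerance = 1e-8)
  expect_equal(pred$label, 1L)
})

test_that("flipping all labels negates decisions and bias", {
  set.seed(11)
  x <- matrix(rnorm(10 * 4), 10, 4)
  y <- rep(c(1, -1), 5)
  K <- build_kernel(x)$train
  m1 <- svm_fit(K, y, C = 2)
  m2 <- svm_fit(K, -y, C = 2)
  expect_equal(m2$b, -m1$b, tolerance = 1e-6)
  expect_equal(svm_decide(m2, K)$decision, -svm_decide(m1, K)$decision,
               tolerance = 1e-6)
})

test_that("separable clusters are classified perfectly at large C", {
  set.seed(21)
  x <- rbind(matrix(rnorm(20, mean = 5), 10, 2),
             matrix(rnorm(20, mean = -5), 10, 2))
  y <- rep(c(1, -1), each = 10)
  K <- build_kernel(x)$train
  model <- svm_fit(K, y, C = 100)
  expect_equal(svm_decide(model, K)$label, y)
})

test_that("fitted models satisfy the KKT conditions to 1e-6", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 12
    x <- matrix(rnorm(n * 5), n, 5)
    y <- rep(c(1, -1), n / 2)
    K <- build_kernel(x)$train
    C <- c(0.1, 1, 10)[1 + seed %% 3]
    model <- svm_fit(K, y, C)
    expect_lt(kkt_residual(model, K), 1e-6)
    expect_lt(abs(sum(model$alpha * y)), 1e-8)
    expect_true(all(model$alpha >= -1e-12 & model$alpha <= C + 1e-12))
  }
})

test_that("the solver matches the interior-point QP oracle", {
  skip_if_not_installed("kernlab")
  for (seed in 1:5) {
    set.seed(seed)
    n <- 14
    x <- matrix(rnorm(n * 6), n, 6)
    y <- sign(rnorm(n)); y[y == 0] <- 1
    if (length(unique(y)) < 2) y[1] <- -y[1]
    K <- build_kernel(x)$train
    model <- svm_fit(K, y, C = 1)
    a_ipop <- ipop_dual(K, y, C = 1)
    expect_equal(dual_objective(model$alpha, K, y),
                 dual_objective(a_ipop, K, y), tolerance = 1e-6)
  }
})

test_that("a support vector scored as a test point reproduces training", {
  set.seed(31)
  x <- matrix(rnorm(8 * 3), 8, 3)
  y <- rep(c(1, -1), 4)
  K <- build_kernel(x)$train
  model <- svm_fit(K, y, C = 1)
  sv <- model$support[1]
  expect_equal(svm_decide(model, K[sv, , drop = FALSE])$decision,
               svm_decide(model, K)$decision[sv], tolerance = 1e-10)
})

test_that("a vertex-weight multi-kernel model equals the single-kernel model", {
  set.seed(41)
  n <- 16
  x1 <- matrix(rnorm(n * 10), n, 10)
  x2 <- matrix(rnorm(n * 4), n, 4)
  x3 <- matrix(rnorm(n * 6), n, 6)
  y <- rep(c(1, -1), n / 2)
  k1 <- build_kernel(x1)$train
  k2 <- build_kernel(x2)$train
  k3 <- build_kernel(x3)$train
  K_vertex <- combine_kernels(list(k1, k2, k3), c(1, 0, 0))
  m_mk <- svm_fit(K_vertex, y, C = 4)
  m_single <- svm_fit(k1, y, C = 4)
  expect_equal(m_mk$alpha, m_single$alpha, tolerance = 1e-8)
  expect_equal(m_mk$b, m_single$b, tolerance = 1e-8)
  expect_equal(svm_decide(m_mk, K_vertex)$decision,
               svm_decide(m_single, k1)$decision, tolerance = 1e-8)
})

test_that("the beta simplex grid has the stars-and-bars cardinality", {
  g3 <- beta_simplex_grid(3, 0.1)
  expect_equal(nrow(g3), choose(12, 2))  # 66
  expect_true(all(abs(rowSums(g3) - 1) < 1e-12))
  expect_true(all(g3 >= 0))
  expect_equal(beta_simplex_grid(1, 0.1), matrix(1, 1, 1))
  expect_equal(nrow(beta_simplex_grid(2, 0.5)), 3)
})

test_that("the default hyperparameter grid spans 2^-5 to 2^5", {
  hg <- hyper_grid()
  expect_length(hg$C_values, 11)
  expect_equal(hg$C_values[1], 2^-5)
  expect_equal(hg$C_values[11], 2^5)
})

test_that("single-block tuning collapses the weight search to the vertex", {
  set.seed(51)
  n <- 12
  x <- rbind(matrix(rnorm(n / 2 * 4, 2), n / 2, 4),
             matrix(rnorm(n / 2 * 4, -2), n / 2, 4))
  y <- rep(c(1, -1), each = n / 2)
  K <- build_kernel(x)$train
  tuned <- mk_tune(list(K), y, hyper_grid(C_values = c(0.5, 1, 2),
                                          beta_step = 0.5),
                   inner_k = 3, seed = 1)
  expect_equal(tuned$beta, 1)
  expect_gt(tuned$accuracy, 0.9)
})

test_that("standardization uses training statistics and drops dead features", {
  set.seed(61)
  train <- cbind(rnorm(10), rep(3, 10), rnorm(10, 5, 2))
  test <- matrix(c(0, 3, 5), 1)
  expect_warning(std <- fold_standardize(train, test), "zero-variance")
  expect_equal(ncol(std$train), 2)
  expect_equal(colMeans(std$train), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(std$train, 2, sd), c(1, 1), tolerance = 1e-12)
  expect_equal(std$test[1, 1], (0 - mean(train[, 1])) / sd(train[, 1]))
})
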