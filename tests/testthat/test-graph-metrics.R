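test_that("star-graph nodal measurements match hand enumeration", {
  A <- star_graph(3)
  nm <- nodal_metrics(A)
  expect_equal(nm$degree, c(3, 1, 1, 1))
  expect_equal(nm$betweenness, c(3, 0, 0, 0))
  expect_equal(nm$efficiency, c(1, 2 / 3, 2 / 3, 2 / 3))
  expect_equal(nm$path_length, c(1, 5 / 3, 5 / 3, 5 / 3))
  expect_equal(nm$clustering, c(0, 0, 0, 0))
})

test_that("every node of a triangle has clustering 1", {
  nm <- nodal_metrics(complete_graph(3))
  expect_equal(nm$clustering, c(1, 1, 1))
})

test_that("betweenness equals exhaustive shortest-path enumeration", {
  for (seed in 1:6) {
    A <- random_adjacency(n = 7, p = 0.4, seed = seed)
    nm <- nodal_metrics(A)
    expect_equal(nm$betweenness, oracle_betweenness(A), tolerance = 1e-10)
  }
})

test_that("nodal metrics agree with adjacency-power oracles on small graphs", {
  for (seed in 7:12) {
    n <- 7
    A <- random_adjacency(n = n, p = 0.35, seed = seed)
    nm <- nodal_metrics(A)
    D <- oracle_distances(A)
    expect_equal(nm$degree, rowSums(A))
    expect_equal(nm$clustering, oracle_clustering(A))
    inv <- 1 / D; diag(inv) <- 0; inv[is.infinite(D)] <- 0
    expect_equal(nm$efficiency, rowSums(inv) / (n - 1))
    for (i in seq_len(n)) {
      d <- D[i, -i]
      d <- d[is.finite(d)]
      expect_equal(nm$path_length[i], if (length(d)) mean(d) else 0)
    }
  }
})

test_that("non-binary or asymmetric input is rejected", {
  A <- star_graph(3)
  B <- A; B[1, 2] <- 2
  expect_error(nodal_metrics(B), "binary")
  B <- A; B[1, 2] <- 0
  expect_error(nodal_metrics(B), "symmetric")
  B <- A; diag(B) <- 1
  expect_error(nodal_metrics(B), "diagonal")
})

test_that("complete-graph global measurements hit their closed forms", {
  gm <- global_metrics(complete_graph(5), nulls = NULL)
  expect_equal(gm[["Eglobal"]], 1)
  expect_equal(gm[["Cp"]], 1)
  expect_equal(gm[["Lp"]], 1)
  # Laplacian spectrum of K_n is {0, n, ..., n}
  expect_equal(gm[["Sr"]], 1)
})

test_that("path-graph global measurements match hand eigen-decomposition", {
  gm <- global_metrics(path_graph(3), nulls = NULL)
  expect_equal(gm[["Lp"]], 4 / 3)
  # Laplacian eigenvalues of P_3 are {0, 1, 3}
  expect_equal(gm[["Sr"]], 1 / 3)
})

test_that("two disjoint triangles achieve modularity 1/2", {
  A <- two_triangles()
  gm <- global_metrics(A, nulls = NULL)
  expect_equal(gm[["Q"]], 0.5)
  # brute force over all partitions of 6 nodes confirms 0.5 is the best
  expect_equal(oracle_best_modularity(A), 0.5)
})

test_that("a star graph is perfectly disassortative", {
  gm <- global_metrics(star_graph(4), nulls = NULL)
  expect_equal(gm[["Ar"]], -1)
})

test_that("a degree-regular graph has undefined assortativity", {
  gm <- global_metrics(complete_graph(4), nulls = NULL)
  expect_true(is.na(gm[["Ar"]]))
})

test_that("global efficiency and path length match the distance oracle", {
  for (seed in 13:18) {
    n <- 7
    A <- random_adjacency(n, p = 0.35, seed = seed)
    gm <- global_metrics(A, nulls = NULL)
    D <- oracle_distances(A)
    up <- upper.tri(D)
    inv <- 1 / D
    expect_equal(gm[["Eglobal"]], sum(inv[up]) / (n * (n - 1) / 2))
    fin <- up & is.finite(D)
    expect_equal(gm[["Lp"]], mean(D[fin]))
    expect_equal(gm[["Cp"]], mean(oracle_clustering(A)))
  }
})

test_that("local efficiency matches direct neighborhood computation", {
  for (seed in 19:22) {
    A <- random_adjacency(7, p = 0.45, seed = seed)
    gm <- global_metrics(A, nulls = NULL)
    vals <- sapply(seq_len(nrow(A)), function(i) {
      nb <- which(A[i, ] == 1)
      if (length(nb) < 2) return(0)
      sub <- A[nb, nb, drop = FALSE]
      Ds <- oracle_distances(sub)
      inv <- 1 / Ds; diag(inv) <- 0; inv[is.infinite(Ds)] <- 0
      sum(inv) / (length(nb) * (length(nb) - 1))
    })
    expect_equal(gm[["Elocal"]], mean(vals))
  }
})

test_that("hierarchy is the negated slope of the log-log regression", {
  set.seed(30)
  A <- random_adjacency(12, p = 0.5, seed = 30)
  gm <- global_metrics(A, nulls = NULL)
  deg <- rowSums(A)
  cc <- oracle_clustering(A)
  ok <- deg >= 2 & cc > 0
  fit <- lm(log(cc[ok]) ~ log(deg[ok]))
  expect_equal(gm[["Hr"]], -unname(coef(fit)[2]), tolerance = 1e-10)
})

test_that("rewired nulls preserve the degree sequence exactly", {
  A <- random_adjacency(15, p = 0.3, seed = 40)
  nulls <- rewire_null(A, null_model_config(n_nulls = 5, seed = 2))
  for (Ak in nulls) {
    expect_equal(rowSums(Ak), rowSums(A))
    expect_equal(unname(Ak), unname(t(Ak)))
    expect_equal(diag(Ak), rep(0, 15))
  }
  expect_false(attr(nulls, "degenerate"))
  # deterministic given seed
  nulls2 <- rewire_null(A, null_model_config(n_nulls = 5, seed = 2))
  expect_identical(lapply(nulls, unname), lapply(nulls2, unname))
})

test_that("a triangle forces identical nulls and unit normalizations", {
  A <- complete_graph(3)
  nulls <- rewire_null(A, null_model_config(n_nulls = 4, seed = 1))
  expect_true(attr(nulls, "degenerate"))
  gm <- global_metrics(A, null_model_config(n_nulls = 4, seed = 1))
  expect_equal(gm[["gamma"]], 1)
  expect_equal(gm[["lambda"]], 1)
  expect_equal(gm[["sigma"]], 1)
})

test_that("random graphs have small-world normalizations near one", {
  # Monte-Carlo oracle: an Erdos-Renyi graph is its own null model, so
  # gamma and lambda should average close to 1
  gammas <- lambdas <- numeric(0)
  for (seed in 1:10) {
    A <- random_adjacency(60, p = 0.2, seed = 100 + seed)
    gm <- global_metrics(A, null_model_config(n_nulls = 3, seed = seed))
    gammas <- c(gammas, gm[["gamma"]])
    lambdas <- c(lambdas, gm[["lambda"]])
  }
  expect_equal(mean(gammas), 1, tolerance = 0.15)
  expect_equal(mean(lambdas), 1, tolerance = 0.15)
})

test_that("relabeling nodes leaves global metrics unchanged and permutes nodal ones", {
  A <- random_adjacency(7, p = 0.5, seed = 55)
  perm <- c(4, 2, 7, 1, 3, 6, 5)
  Ap <- A[perm, perm]
  gm <- global_metrics(A, nulls = NULL)
  gmp <- global_metrics(Ap, nulls = NULL)
  expect_equal(gmp[setdiff(names(gmp), c("gamma", "lambda", "sigma"))],
               gm[setdiff(names(gm), c("gamma", "lambda", "sigma"))],
               tolerance = 1e-10)
  nm <- nodal_metrics(A)
  nmp <- nodal_metrics(Ap)
  for (col in names(nm)) {
    expect_equal(nmp[[col]], nm[[col]][perm], tolerance = 1e-10)
  }
})

test_that("global efficiency is non-decreasing along a nested stack", {
  set.seed(60)
  W <- pearson_fbn(matrix(rnorm(100 * 12), 100, 12))
  stack <- threshold_stack(W, sparsity_grid(0.1, 0.5, 0.05))
  eg <- sapply(stack$graphs, function(A) {
    global_metrics(A, nulls = NULL)[["Eglobal"]]
  })
  expect_true(all(diff(eg) >= -1e-12))
})

test_that("threshold AUC aggregation follows its two modes", {
  grid <- sparsity_grid()
  vals <- 1:49
  expect_equal(as.numeric(auc_over_thresholds(vals, grid)), 1225)
  expect_equal(as.numeric(auc_over_thresholds(vals, grid, mode = "step")),
               12.25)
  expect_equal(as.numeric(auc_over_thresholds(rep(0, 49), grid)), 0)
  expect_equal(as.numeric(auc_over_thresholds(rep(1, 49), grid)), 49)
  expect_error(auc_over_thresholds(1:10, grid), "grid")
  expect_error(auc_over_thresholds(c(1:48, NA), grid), "missing")
})

test_that("the empty graph is rejected", {
  A <- matrix(0L, 4, 4)
  expect_error(global_metrics(A, nulls = NULL), "empty")
})
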