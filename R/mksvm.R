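#' Standardize features with training-fold statistics
#'
#' Z-scores each feature using mean and sd computed on the training rows
#' only; the same transform is applied to optional test rows.
#' Zero-variance training features are dropped with a warning (their
#' z-score is undefined).
#'
#' @param train training feature matrix (subjects x features).
#' @param test optional matrix with the same columns.
#' @return list with `train`, `test` (or NULL), and `kept` column indices.
#' @export
fold_standardize <- function(train, test = NULL) {
  mu <- colMeans(train)
  sd_ <- apply(train, 2L, stats::sd)
  kept <- which(sd_ > 0)
  if (length(kept) < ncol(train)) {
    warning(ncol(train) - length(kept),
            " zero-variance feature(s) dropped during standardization")
  }
  if (length(kept) == 0L) stop("no features left after standardization")
  scale_rows <- function(x) {
    sweep(sweep(x[, kept, drop = FALSE], 2L, mu[kept]), 2L, sd_[kept], "/")
  }
  list(train = scale_rows(train),
       test = if (is.null(test)) NULL else scale_rows(test),
       kept = kept)
}

#' Linear kernel block with training-diagonal normalization
#'
#' Computes inner-product Gram matrices and divides by the mean of the
#' training Gram diagonal so the per-modality blocks are on commensurable
#' scales. Test rows use the same training-derived normalizer.
#'
#' @param train standardized training feature matrix.
#' @param test optional standardized test feature matrix.
#' @return list with `train` (n_train x n_train Gram), `test`
#'   (n_test x n_train cross-Gram or NULL), and `normalizer`.
#' @export
build_kernel <- function(train, test = NULL) {
  K <- tcrossprod(train)
  normalizer <- mean(diag(K))
  if (normalizer <= 0) normalizer <- 1
  list(train = K / normalizer,
       test = if (is.null(test)) NULL else tcrossprod(test, train) / normalizer,
       normalizer = normalizer)
}

#' Convex combination of kernel blocks
#'
#' @param blocks list of conformable Gram matrices.
#' @param beta nonnegative weights summing to 1 (one per block).
#' @return the element-wise weighted sum.
#' @export
combine_kernels <- function(blocks, beta) {
  if (length(blocks) != length(beta)) stop("one weight per block required")
  if (any(beta < -1e-12) || abs(sum(beta) - 1) > 1e-8) {
    stop("kernel weights must be nonnegative and sum to 1")
  }
  dims <- vapply(blocks, dim, numeric(2L))
  if (any(dims != dims[, 1L])) stop("kernel blocks are not conformable")
  out <- beta[1L] * blocks[[1L]]
  for (m in seq_along(blocks)[-1L]) out <- out + beta[m] * blocks[[m]]
  out
}

#' Fit a soft-margin SVM on a precomputed kernel (SMO dual solver)
#'
#' Solves the box-constrained dual
#' `max sum(alpha) - 0.5 * sum_ij alpha_i alpha_j y_i y_j K_ij` subject to
#' `sum(alpha_i y_i) = 0`, `0 <= alpha_i <= C`, by sequential minimal
#' optimization with maximal-violating-pair working-set selection. The
#' bias `b` is the average of the Karush-Kuhn-Tucker conditions over free
#' (non-bound) support vectors, or the feasibility-interval midpoint when
#' none are free.
#'
#' The solver runs SMO to a coarse duality gap (1e-3, where SMO is fast
#' and cannot cycle at floating-point resolution) and then refines the
#' solution with an active-set step that solves the free-variable KKT
#' system exactly, leaving residuals near machine precision.
#'
#' @param K combined Gram matrix (training x training).
#' @param y labels in {+1, -1}.
#' @param C box constraint.
#' @param tol maximum acceptable KKT violation (default 1e-8).
#' @param max_iter iteration cap for the SMO phase.
#' @return object of class `svm_model` with `alpha`, `b`, `C`, `y`,
#'   `support` (indices with alpha > 0), and the final KKT residual.
#' @export
svm_fit <- function(K, y, C, tol = 1e-8, max_iter = NULL) {
  n <- length(y)
  stopifnot(nrow(K) == n, ncol(K) == n, all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2L) stop("both classes required")
  if (C <= 0) stop("C must be positive")
  if (is.null(max_iter)) max_iter <- max(20000L, 200L * n)
  smo_tol <- max(tol, 1e-3)
  alpha <- numeric(n)
  grad <- rep(-1, n)  # gradient of 0.5 a'Qa - e'a at a = 0
  Q <- K * tcrossprod(y)
  dK <- diag(K)
  bound_eps <- 1e-10 * max(1, C)
  it <- 0L
  repeat {
    it <- it + 1L
    up <- (y > 0 & alpha < C - bound_eps) | (y < 0 & alpha > bound_eps)
    lo <- (y > 0 & alpha > bound_eps) | (y < 0 & alpha < C - bound_eps)
    G_up <- -y * grad
    # second-order working-set selection (LIBSVM WSS2): i maximizes the
    # violation; j maximizes the guaranteed objective decrease, which
    # avoids the slow zigzag of the purely first-order pair
    i <- which(up)[which.max(G_up[up])]
    if (!length(i) || !any(lo)) {
      gap <- 0
      break
    }
    gap <- G_up[i] - min(G_up[lo])
    if (gap < smo_tol || it > max_iter) break
    cand <- which(lo & G_up < G_up[i])
    b_j <- G_up[i] - G_up[cand]
    a_j <- pmax(dK[i] + dK[cand] - 2 * K[i, cand], 1e-12)
    j <- cand[which.max(b_j^2 / a_j)]
    # two-variable analytic sub-problem along the feasible direction
    quad <- Q[i, i] + Q[j, j] - 2 * y[i] * y[j] * Q[i, j]
    if (quad <= 1e-12) quad <- 1e-12
    delta <- (G_up[i] - G_up[j]) / quad
    # max feasible step for alpha_i (direction +y_i) and alpha_j (-y_j)
    step_i <- if (y[i] > 0) C - alpha[i] else alpha[i]
    step_j <- if (y[j] > 0) alpha[j] else C - alpha[j]
    delta <- min(delta, step_i, step_j)
    # land exactly on the box when the step is binding, so later
    # iterations are never clipped to slivers left by rounding
    alpha[i] <- if (delta == step_i) {
      if (y[i] > 0) C else 0
    } else alpha[i] + y[i] * delta
    alpha[j] <- if (delta == step_j) {
      if (y[j] > 0) 0 else C
    } else alpha[j] - y[j] * delta
    grad <- grad + delta * (y[i] * Q[, i] - y[j] * Q[, j])
  }
  if (it > max_iter && gap > smo_tol * 1.01) {
    stop("SMO did not converge within ", max_iter,
         " iterations (gap ", signif(gap, 3), ")")
  }
  polished <- polish_dual(alpha, K, y, C)
  if (!is.null(polished)) {
    alpha <- polished$alpha
    b <- polished$b
  } else {
    # b from free support vectors' stationarity: y_i * f(x_i) = 1
    f_no_b <- as.numeric(K %*% (alpha * y))
    free <- alpha > 1e-8 & alpha < C - 1e-8
    b <- if (any(free)) {
      mean(y[free] - f_no_b[free])
    } else {
      # midpoint of the feasibility interval of -y_i grad_i
      up <- (y > 0 & alpha < C - bound_eps) | (y < 0 & alpha > bound_eps)
      lo <- (y > 0 & alpha > bound_eps) | (y < 0 & alpha < C - bound_eps)
      G_up <- -y * grad
      (max(G_up[up]) + min(G_up[lo])) / 2
    }
  }
  resid <- kkt_violation(alpha, b, K, y, C)
  if (resid > max(tol, 1e-6)) {
    stop("SVM solver did not reach the KKT tolerance (residual ",
         signif(resid, 3), ")")
  }
  structure(list(alpha = alpha, b = b, C = C, y = y,
                 support = which(alpha > 1e-8), kkt_residual = resid),
            class = "svm_model")
}

#' Largest violation of the KKT optimality conditions of a dual solution
#' @keywords internal
#' @noRd
kkt_violation <- function(alpha, b, K, y, C) {
  f <- as.numeric(K %*% (alpha * y)) + b
  yf <- y * f
  eps_b <- 1e-8 * max(1, C)
  free <- alpha > eps_b & alpha < C - eps_b
  at_zero <- alpha <= eps_b
  at_C <- alpha >= C - eps_b
  max(abs(sum(alpha * y)),
      if (any(free)) max(abs(yf[free] - 1)) else 0,
      if (any(at_zero)) max(pmax(0, 1 - yf[at_zero])) else 0,
      if (any(at_C)) max(pmax(0, yf[at_C] - 1)) else 0)
}

#' Active-set refinement of an approximate dual solution
#'
#' Given the near-optimal active set produced by the SMO phase, solves
#' the equality-constrained KKT system over the free variables exactly
#' and migrates variables across the box boundary until the optimality
#' conditions hold. Returns NULL if it cannot converge (the caller then
#' falls back to the unpolished iterate).
#' @keywords internal
#' @noRd
polish_dual <- function(alpha, K, y, C, max_rounds = 200L) {
  n <- length(y)
  Q <- K * tcrossprod(y)
  eps_b <- 1e-8 * max(1, C)
  # status: 0 = at lower bound, 1 = free, 2 = at upper bound
  status <- ifelse(alpha <= eps_b, 0L, ifelse(alpha >= C - eps_b, 2L, 1L))
  alpha <- ifelse(status == 0L, 0, ifelse(status == 2L, C, alpha))
  objective <- function(a) 0.5 * sum(a * (Q %*% a)) - sum(a)
  best <- NULL
  for (round in seq_len(max_rounds)) {
    fr <- which(status == 1L)
    if (length(fr) == 0L) {
      # everything at a bound: free the maximal violating pair so the
      # KKT system has unknowns to solve for
      G_up <- -y * (as.numeric(Q %*% alpha) - 1)
      up <- (y > 0 & status != 2L) | (y < 0 & status != 0L)
      lo <- (y > 0 & status != 0L) | (y < 0 & status != 2L)
      if (!any(up) || !any(lo)) break
      i <- which(up)[which.max(G_up[up])]
      j <- which(lo)[which.min(G_up[lo])]
      if (i == j) break
      status[c(i, j)] <- 1L
      fr <- which(status == 1L)
    }
    bc <- which(status == 2L)
    rhs1 <- rep(1, length(fr))
    eq_rhs <- 0
    if (length(bc)) {
      rhs1 <- rhs1 - as.numeric(Q[fr, bc, drop = FALSE] %*% rep(C, length(bc)))
      eq_rhs <- -C * sum(y[bc])
    }
    M <- rbind(cbind(Q[fr, fr, drop = FALSE] + diag(1e-12, length(fr)),
                     y[fr]),
               c(y[fr], 0))
    sol <- tryCatch(solve(M, c(rhs1, eq_rhs)), error = function(e) NULL)
    if (is.null(sol) || anyNA(sol)) break
    a_target <- sol[seq_along(fr)]
    b <- sol[length(sol)]
    # damped step: walk from the current iterate toward the KKT target
    # of this active set, stopping at the first box face; monotone in
    # the objective, which rules out the cycling of undamped pivoting
    d <- a_target - alpha[fr]
    theta <- 1
    blocking <- 0L
    for (k in seq_along(fr)) {
      if (d[k] < -1e-15 && alpha[fr[k]] + theta * d[k] < 0) {
        theta <- alpha[fr[k]] / -d[k]; blocking <- k
      } else if (d[k] > 1e-15 && alpha[fr[k]] + theta * d[k] > C) {
        theta <- (C - alpha[fr[k]]) / d[k]; blocking <- k
      }
    }
    alpha[fr] <- alpha[fr] + theta * d
    if (blocking > 0L) {
      hit_low <- alpha[fr[blocking]] <= eps_b
      alpha[fr[blocking]] <- if (hit_low) 0 else C
      status[fr[blocking]] <- if (hit_low) 0L else 2L
      next
    }
    alpha[fr] <- pmin(pmax(a_target, 0), C)
    g <- as.numeric(Q %*% alpha) - 1 + b * y
    viol <- numeric(n)
    viol[status == 0L] <- pmax(0, -g[status == 0L])
    viol[status == 2L] <- pmax(0, g[status == 2L])
    cur <- list(alpha = alpha, b = b, viol = max(viol),
                obj = objective(alpha))
    if (is.null(best) || cur$obj < best$obj ||
        (cur$obj <= best$obj + 1e-12 && cur$viol < best$viol)) {
      best <- cur
    }
    if (max(viol) <= 1e-9) return(list(alpha = alpha, b = b))
    status[which.max(viol)] <- 1L
  }
  if (!is.null(best)) list(alpha = best$alpha, b = best$b) else NULL
}

#' Decision values and labels for test points
#'
#' Evaluates `f(x) = sum_i y_i alpha_i K(x_i, x) + b`; the predicted label
#' is +1 when f > 0 and -1 otherwise (ties at exactly 0 go to the
#' negative class).
#'
#' @param model an `svm_model`.
#' @param K_test n_test x n_train kernel rows against the training
#'   subjects (already combined across blocks with the training beta).
#' @return list with `decision` and `label` vectors.
#' @export
svm_decide <- function(model, K_test) {
  if (ncol(K_test) != length(model$alpha)) {
    stop("test kernel has ", ncol(K_test), " columns; model was trained on ",
         length(model$alpha), " subjects")
  }
  f <- as.numeric(K_test %*% (model$alpha * model$y)) + model$b
  list(decision = f, label = ifelse(f > 0, 1L, -1L))
}

#' Hyperparameter grid for the multi-kernel SVM
#'
#' @param C_values box-constraint candidates (default 2^-5 ... 2^5, 11
#'   values).
#' @param beta_step simplex grid spacing for the kernel weights (default
#'   0.1, giving 66 candidates over 3 blocks).
#' @return object of class `hyper_grid`.
#' @export
hyper_grid <- function(C_values = 2^(-5:5), beta_step = 0.1) {
  if (any(C_values <= 0)) stop("all C values must be positive")
  if (beta_step <= 0 || beta_step > 1) stop("beta_step must be in (0, 1]")
  structure(list(C_values = C_values, beta_step = beta_step),
            class = "hyper_grid")
}

#' Enumerate the simplex grid of kernel weights
#'
#' All vectors of multiples of `step` over `n_blocks` coordinates that
#' sum to 1 (stars-and-bars enumeration).
#'
#' @param n_blocks number of kernel blocks.
#' @param step grid spacing (1/step must be integral).
#' @return matrix with one candidate weight vector per row.
#' @export
beta_simplex_grid <- function(n_blocks, step = 0.1) {
  k <- round_half_away(1 / step)
  if (abs(k * step - 1) > 1e-8) stop("1/step must be an integer")
  if (n_blocks == 1L) return(matrix(1, 1L, 1L))
  combos <- function(total, slots) {
    if (slots == 1L) return(matrix(total, 1L, 1L))
    do.call(rbind, lapply(0:total, function(a) {
      cbind(a, combos(total - a, slots - 1L))
    }))
  }
  combos(k, n_blocks) / k
}

#' Deterministic stratified k-fold assignment
#' @keywords internal
#' @noRd
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Tune C and the kernel weights by inner cross-validation
#'
#' Exhaustive search over the C grid and the beta simplex grid, scored by
#' stratified inner-CV accuracy on the training subjects. Ties are broken
#' toward the most uniform beta (largest entropy), then the smallest C.
#'
#' @param blocks list of training Gram matrices (one per used block).
#' @param y training labels.
#' @param grid a [hyper_grid()].
#' @param inner_k number of inner folds (default 5).
#' @param seed seed for the inner fold assignment.
#' @return list with `C`, `beta`, `accuracy` (best inner-CV accuracy).
#' @export
mk_tune <- function(blocks, y, grid = hyper_grid(), inner_k = 5L, seed = 1L) {
  n_blocks <- length(blocks)
  betas <- beta_simplex_grid(n_blocks, grid$beta_step)
  k <- min(inner_k, min(table(y)))
  if (k < 2L) stop("too few subjects per class for inner cross-validation")
  fold <- stratified_folds(y, k, seed)
  best <- NULL
  for (bi in seq_len(nrow(betas))) {
    beta <- betas[bi, ]
    K <- combine_kernels(blocks, beta)
    ent <- -sum(ifelse(beta > 0, beta * log(beta), 0))
    for (C in grid$C_values) {
      correct <- 0L
      for (f in seq_len(k)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2L) next
        model <- svm_fit(K[tr, tr, drop = FALSE], y[tr], C)
        pred <- svm_decide(model, K[!tr, tr, drop = FALSE])$label
        correct <- correct + sum(pred == y[!tr])
      }
      acc <- correct / length(y)
      if (is.null(best) || acc > best$accuracy + 1e-12 ||
          (abs(acc - best$accuracy) <= 1e-12 &&
           (ent > best$entropy + 1e-12 ||
            (abs(ent - best$entropy) <= 1e-12 && C < best$C)))) {
        best <- list(C = C, beta = beta, accuracy = acc, entropy = ent)
      }
    }
  }
  best[c("C", "beta", "accuracy")]
}
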