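# Feature matrices with a clean two-cluster structure in the connection
# block, used to exercise the LOOCV machinery without graph metrics.
separable_features <- function(n_per = 8, n_feat = 30, gap = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  x <- matrix(rnorm(n * n_feat), n, n_feat)
  x[1:n_per, 1:10] <- x[1:n_per, 1:10] + gap
  labels <- rep(c(1, -1), each = n_per)
  glob <- matrix(rnorm(n * 11), n, 11,
                 dimnames = list(NULL, GLOBAL_METRIC_NAMES))
  list(connection = x, global = glob, nodal = matrix(rnorm(n * 20), n, 20),
       index_maps = NULL) -> f
  list(features = f, labels = labels)
}

small_hyper <- hyper_grid(C_values = 2^c(-2, 0, 2), beta_step = 0.5)

test_that("leave-one-out produces one fold record per subject", {
  d <- separable_features()
  run <- loocv_run(d$features, d$labels, blocks = "connection",
                   grid = small_hyper, inner_k = 3, seed = 1)
  expect_equal(nrow(run$records), 16)
  expect_equal(run$records$subject, 1:16)
  expect_length(run$masks, 16)
})

test_that("a cleanly separable cohort is classified perfectly", {
  d <- separable_features(gap = 4)
  run <- loocv_run(d$features, d$labels, blocks = "connection",
                   grid = small_hyper, inner_k = 3, seed = 1)
  expect_equal(run$records$predicted, d$labels)
  cm <- confusion_metrics(run$records)
  expect_equal(cm$accuracy, 1)
})

test_that("a fold's trained model never sees its held-out subject", {
  d <- separable_features(gap = 2, seed = 5)
  run1 <- loocv_run(d$features, d$labels, blocks = "connection",
                    grid = small_hyper, inner_k = 3, seed = 2)
  corrupted <- d$features
  corrupted$connection[7, ] <- 100
  run2 <- loocv_run(corrupted, d$labels, blocks = "connection",
                    grid = small_hyper, inner_k = 3, seed = 2)
  # fold 7 trains on the other 15 subjects, so its selection mask and
  # tuned hyperparameters cannot react to the corruption ...
  expect_identical(run1$masks[[7]], run2$masks[[7]])
  expect_equal(run1$records$C[7], run2$records$C[7])
  expect_equal(run1$records$beta_connection[7],
               run2$records$beta_connection[7])
  # ... only its prediction (through the test kernel rows) can
  expect_false(isTRUE(all.equal(run1$records$decision[7],
                                run2$records$decision[7])))
})

test_that("confusion metrics follow their defining ratios", {
  # TP = 3, FN = 2, TN = 4, FP = 1
  true <- c(rep(1, 5), rep(-1, 5))
  pred <- c(1, 1, 1, -1, -1, -1, -1, -1, -1, 1)
  cm <- confusion_metrics(true, pred)
  expect_equal(cm$accuracy, 0.7)
  expect_equal(cm$sensitivity, 0.6)
  expect_equal(cm$specificity, 0.8)
  expect_equal(sum(cm$counts), 10)
})

test_that("degenerate predictors hit the boundary values", {
  true <- c(1, 1, -1, -1)
  expect_equal(confusion_metrics(true, c(1, 1, 1, 1))$specificity, 0)
  expect_equal(confusion_metrics(true, c(1, 1, 1, 1))$sensitivity, 1)
  all_right <- confusion_metrics(true, true)
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)
  # absent positive class: sensitivity undefined, flagged not thrown
  cm <- confusion_metrics(c(-1, -1), c(-1, 1))
  expect_true(is.na(cm$sensitivity))
})

test_that("accuracy decomposes into class-weighted sensitivity and specificity", {
  set.seed(9)
  for (rep in 1:5) {
    true <- sample(c(1, -1), 20, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(true)) < 2) next
    pred <- sample(c(1, -1), 20, replace = TRUE)
    cm <- confusion_metrics(true, pred)
    p <- sum(true > 0); n <- sum(true < 0)
    expect_equal(cm$accuracy,
                 (cm$sensitivity * p + cm$specificity * n) / (p + n))
  }
})

test_that("ROC area counts concordant pairs", {
  scores <- c(0.9, 0.4, 0.5, 0.1)
  labels <- c(1, 1, -1, -1)
  roc <- roc_auc(scores, labels)
  expect_equal(roc$auc, 0.75)  # 3 of 4 concordant pairs
  expect_equal(roc_auc(c(3, 2, 1, 0), labels)$auc, 1)
  expect_equal(roc_auc(-scores, labels)$auc, 1 - 0.75)
})

test_that("the ROC curve is monotone and spans the unit square", {
  set.seed(15)
  scores <- rnorm(30)
  labels <- rep(c(1, -1), 15)
  roc <- roc_auc(scores, labels)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
  expect_equal(range(roc$fpr), c(0, 1))
  expect_equal(range(roc$tpr), c(0, 1))
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- rnorm(40)
  labels <- sample(rep(c(1, -1), 20))
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c(-1, 1),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("constant decision values warn and fall back to chance", {
  expect_warning(roc <- roc_auc(rep(0.3, 6), rep(c(1, -1), 3)), "constant")
  expect_equal(roc$auc, 0.5)
})

test_that("a curve compared against itself is not significant", {
  set.seed(31)
  scores <- rnorm(20)
  labels <- rep(c(1, -1), 10)
  dl <- delong_test(scores, scores, labels)
  expect_equal(dl$statistic, 0)
  expect_equal(dl$p_value, 1)
})

test_that("swapping the two methods negates the statistic", {
  set.seed(37)
  labels <- rep(c(1, -1), each = 15)
  a <- rnorm(30) + (labels > 0) * 1.5
  b <- rnorm(30) + (labels > 0) * 0.5
  ab <- delong_test(a, b, labels)
  ba <- delong_test(b, a, labels)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  expect_gt(ab$auc_a, ab$auc_b)
})

test_that("the DeLong test matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  labels <- rep(c(1, -1), each = 20)
  base <- rnorm(40)
  a <- base + (labels > 0) * 1.2 + rnorm(40, sd = 0.5)
  b <- base + (labels > 0) * 0.7 + rnorm(40, sd = 0.5)
  ours <- delong_test(a, b, labels)
  ra <- pROC::roc(labels, a, levels = c(-1, 1), direction = "<",
                  quiet = TRUE)
  rb <- pROC::roc(labels, b, levels = c(-1, 1), direction = "<",
                  quiet = TRUE)
  theirs <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ours$p_value, theirs$p.value, tolerance = 1e-10)
})

test_that("the seven method configurations are the expected block sets", {
  cfgs <- method_configs()
  expect_named(cfgs, c("C", "N", "G", "C+G", "C+N", "G+N", "C+G+N"))
  expect_equal(cfgs[["C+G+N"]], c("connection", "global", "nodal"))
  expect_equal(cfgs[["C"]], "connection")
  expect_error(method_configs("X"), "unknown")
})
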