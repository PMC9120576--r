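#' The seven method configurations
#'
#' Single-block and combined-block classifiers: connection weights (C),
#' global metric AUCs (G), nodal metric AUCs (N), and their combinations
#' up to the full three-kernel model C+G+N.
#'
#' @param ids subset of identifiers to return (default all seven).
#' @return named list mapping identifier to the block names it uses.
#' @export
method_configs <- function(ids = c("C", "N", "G", "C+G", "C+N", "G+N",
                                   "C+G+N")) {
  all <- list(
    "C" = "connection",
    "N" = "nodal",
    "G" = "global",
    "C+G" = c("connection", "global"),
    "C+N" = c("connection", "nodal"),
    "G+N" = c("global", "nodal"),
    "C+G+N" = c("connection", "global", "nodal"))
  missing <- setdiff(ids, names(all))
  if (length(missing)) stop("unknown method id(s): ",
                            paste(missing, collapse = ", "))
  all[ids]
}

#' Leave-one-out cross-validation for one method configuration
#'
#' For each subject in turn: hold it out, run t-test feature selection,
#' training-fold standardization, kernel construction, inner-CV
#' hyperparameter tuning, and the final SVM fit on the remaining
#' subjects, then predict the held-out subject. No held-out information
#' enters any training computation.
#'
#' @param features cohort feature matrices from [bind_feature_blocks()].
#' @param labels vector in {+1, -1}, one per subject.
#' @param blocks block names used by this method (see [method_configs()]).
#' @param alpha t-test selection level (default 0.05).
#' @param grid a [hyper_grid()].
#' @param inner_k inner-CV folds (default 5).
#' @param seed seed controlling inner fold assignment.
#' @param var_equal pooled (default) or Welch selection t-test.
#' @return list with `records` (one row per subject: true/predicted
#'   label, decision value, tuned C, beta, selected-feature counts) and
#'   `masks` (the per-fold `selection_mask` objects, for consensus
#'   analysis).
#' @export
loocv_run <- function(features, labels, blocks = c("connection", "global",
                                                   "nodal"),
                      alpha = 0.05, grid = hyper_grid(), inner_k = 5L,
                      seed = 1L, var_equal = TRUE) {
  n <- length(labels)
  if (n < 4L) stop("need at least 4 subjects for leave-one-out validation")
  if (length(unique(sign(labels))) < 2L) stop("both classes required")
  records <- vector("list", n)
  masks <- vector("list", n)
  for (s in seq_len(n)) {
    tr <- setdiff(seq_len(n), s)
    y_tr <- labels[tr]
    if (length(unique(sign(y_tr))) < 2L) {
      stop("fold ", s, " has a single-class training set")
    }
    train_blocks <- lapply(features[blocks], function(x) {
      x[tr, , drop = FALSE]
    })
    names(train_blocks) <- blocks
    mask <- ttest_select(train_blocks, y_tr, alpha = alpha,
                         blocks = blocks, var_equal = var_equal)
    grams <- lapply(blocks, function(b) {
      sel <- mask[[b]]$mask
      std <- fold_standardize(features[[b]][tr, sel, drop = FALSE],
                              features[[b]][s, sel, drop = FALSE])
      build_kernel(std$train, std$test)
    })
    tuned <- mk_tune(lapply(grams, `[[`, "train"), y_tr, grid = grid,
                     inner_k = inner_k, seed = seed + s)
    K_train <- combine_kernels(lapply(grams, `[[`, "train"), tuned$beta)
    model <- svm_fit(K_train, y_tr, tuned$C)
    K_test <- combine_kernels(lapply(grams, `[[`, "test"), tuned$beta)
    pred <- svm_decide(model, K_test)
    rec <- data.frame(subject = s, true = labels[s],
                      predicted = pred$label, decision = pred$decision,
                      C = tuned$C, inner_accuracy = tuned$accuracy)
    for (bi in seq_along(blocks)) {
      rec[[paste0("beta_", blocks[bi])]] <- tuned$beta[bi]
      rec[[paste0("n_selected_", blocks[bi])]] <- sum(mask[[blocks[bi]]]$mask)
    }
    rec$fallback <- any(vapply(mask, function(m) m$fallback, logical(1L)))
    records[[s]] <- rec
    masks[[s]] <- mask
  }
  list(records = do.call(rbind, records), masks = masks, blocks = blocks)
}

#' Accuracy, sensitivity, and specificity from fold records
#'
#' Positive class is +1. A zero denominator yields `NA` for the affected
#' rate rather than an error.
#'
#' @param true,predicted label vectors in {+1, -1} (or a `records`
#'   data.frame passed as `true` with `predicted` missing).
#' @return list with `accuracy`, `sensitivity`, `specificity`, and the
#'   confusion `counts` (TP, FP, TN, FN).
#' @export
confusion_metrics <- function(true, predicted = NULL) {
  if (is.data.frame(true)) {
    predicted <- true$predicted
    true <- true$true
  }
  stopifnot(length(true) == length(predicted))
  tp <- sum(true > 0 & predicted > 0)
  fn <- sum(true > 0 & predicted < 0)
  tn <- sum(true < 0 & predicted < 0)
  fp <- sum(true < 0 & predicted > 0)
  total <- tp + fp + tn + fn
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = safe_div(tp + tn, total),
       sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp),
       counts = c(TP = tp, FP = fp, TN = tn, FN = fn))
}

#' ROC curve and AUC from continuous decision values
#'
#' The curve sweeps the decision threshold over the observed scores; the
#' area equals the Mann-Whitney U statistic normalized by the number of
#' positive-negative pairs (midrank handling of ties).
#'
#' @param scores continuous decision values (larger = more positive).
#' @param labels true labels in {+1, -1}.
#' @return list with `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes required")
  if (length(unique(scores)) == 1L) {
    warning("constant decision values: AUC is 0.5 by convention")
    return(list(fpr = c(0, 1), tpr = c(0, 1),
                thresholds = c(Inf, unique(scores)), auc = 0.5))
  }
  r <- rank(scores)  # midranks
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n1, numeric(1L))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n0, numeric(1L))
  list(fpr = c(0, fpr), tpr = c(0, tpr), thresholds = c(Inf, thr),
       auc = auc)
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors computed on the same subjects
#' using the structural-component (midrank) estimate of the variance of
#' the correlated AUC difference and a two-sided normal p-value.
#'
#' @param scores_a,scores_b decision-value vectors from two methods on
#'   the same subjects.
#' @param labels true labels in {+1, -1}.
#' @return list with `auc_a`, `auc_b`, `difference`, `statistic` (z),
#'   `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  pos <- labels > 0
  m <- sum(pos); n <- sum(!pos)
  if (m == 0L || n == 0L) stop("both classes required")
  comp <- function(s) {
    x <- s[pos]; y <- s[!pos]
    tz <- rank(c(x, y))
    tx <- rank(x)
    ty <- rank(y)
    theta <- (sum(tz[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
    v10 <- (tz[seq_len(m)] - tx) / n              # positive components
    v01 <- 1 - (tz[m + seq_len(n)] - ty) / m      # negative components
    list(theta = theta, v10 = v10, v01 = v01)
  }
  a <- comp(scores_a); b <- comp(scores_b)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- a$theta - b$theta
  if (var_diff <= 1e-24) {
    z <- 0
    p <- if (abs(diff) < 1e-12) 1 else 0
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = a$theta, auc_b = b$theta, difference = diff,
       statistic = z, p_value = p)
}
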