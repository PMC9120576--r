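#' Group-level mean connectivity networks
#'
#' Element-wise mean of the subjects' connectivity matrices within each
#' group.
#'
#' @param matrices list of connectivity matrices (same dimensions).
#' @param labels vector in {+1, -1}, one per matrix.
#' @return list with one mean matrix per group, named `pos` and `neg`.
#' @export
group_mean_network <- function(matrices, labels) {
  stopifnot(length(matrices) == length(labels))
  mean_of <- function(idx) {
    if (length(idx) == 0L) stop("empty group")
    Reduce(`+`, matrices[idx]) / length(idx)
  }
  list(pos = mean_of(which(labels > 0)), neg = mean_of(which(labels < 0)))
}

#' Hub regions of a group-level network
#'
#' Ranks regions by a group-level centrality score — the weighted degree
#' (row sums excluding the diagonal) of a mean network, or any supplied
#' per-region score vector — and returns the top fraction. Ties are
#' broken by ascending region index so the table is deterministic.
#'
#' @param x mean connectivity matrix or a named per-region score vector.
#' @param proportion fraction of regions returned (default 0.05, the
#'   usual top-5% hub rule).
#' @param measure label recorded in the output (e.g. "degree",
#'   "betweenness").
#' @return data.frame with columns `region`, `score`, `rank`, sorted by
#'   descending score; attribute `proportion`.
#' @export
hub_nodes <- function(x, proportion = 0.05, measure = "degree") {
  if (!(proportion > 0 && proportion < 1)) {
    stop("proportion must be in (0, 1)")
  }
  if (is.matrix(x)) {
    score <- rowSums(x) - diag(x)
    regions <- rownames(x) %||% sprintf("R%03d", seq_len(nrow(x)))
  } else {
    score <- as.numeric(x)
    regions <- names(x) %||% sprintf("R%03d", seq_along(x))
  }
  n <- length(score)
  k <- round_half_away(proportion * n)
  if (k < 1L) stop("proportion ", proportion, " selects zero of ", n,
                   " regions")
  ord <- order(-score, seq_len(n))
  top <- ord[seq_len(k)]
  structure(data.frame(region = regions[top], score = score[top],
                       rank = seq_len(k), measure = measure),
            proportion = proportion)
}

#' Between-group comparison of metric features
#'
#' Two-sample two-tailed t-test per column (global metric AUCs, or
#' per-region degree/betweenness AUCs) with group means and standard
#' deviations, sorted by ascending p. Significance is flagged at the
#' uncorrected level as is conventional in these group tables; a
#' Benjamini-Hochberg column is emitted alongside.
#'
#' @param x numeric matrix, subjects x features (columns named).
#' @param labels vector in {+1, -1}.
#' @param alpha significance level for the flag (default 0.05).
#' @param var_equal pooled (default) or Welch t-test.
#' @return data.frame with columns `feature`, `mean_pos`, `sd_pos`,
#'   `mean_neg`, `sd_neg`, `t`, `p`, `p_bh`, `significant`.
#' @export
compare_group_metrics <- function(x, labels, alpha = 0.05,
                                  var_equal = TRUE) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  pos <- labels > 0
  if (!any(pos) || all(pos)) stop("both groups must be non-empty")
  tt <- col_ttest(x, labels, var_equal = var_equal)
  sd_grp <- function(rows) apply(x[rows, , drop = FALSE], 2L, stats::sd)
  p <- tt$p
  # zero pooled variance with equal means is not evidence either way
  zero_var <- tt$t == 0 & sd_grp(pos) == 0 & sd_grp(!pos) == 0
  p[zero_var & tt$mean_diff == 0] <- NA_real_
  out <- data.frame(
    feature = colnames(x) %||% paste0("f", seq_len(ncol(x))),
    mean_pos = colMeans(x[pos, , drop = FALSE]),
    sd_pos = sd_grp(pos),
    mean_neg = colMeans(x[!pos, , drop = FALSE]),
    sd_neg = sd_grp(!pos),
    t = tt$t, p = p,
    p_bh = stats::p.adjust(p, method = "BH"),
    row.names = NULL)
  out$significant <- !is.na(out$p) & out$p < alpha
  out[order(out$p), , drop = FALSE]
}
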