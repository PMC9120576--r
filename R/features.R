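#' Assemble the three feature blocks for one subject
#'
#' Blocks, in fixed deterministic order: `connection` — the upper-triangle
#' connection weights in lexicographic (i, j) order (length n(n-1)/2);
#' `global` — the 11 global metric AUCs in [GLOBAL_METRIC_NAMES] order;
#' `nodal` — the 5 x n nodal metric AUCs, metric-major then region index.
#'
#' @param W connectivity matrix from [pearson_fbn()].
#' @param aucs output of [metric_aucs()] for the same subject.
#' @return object of class `feature_blocks`: list of the three named
#'   numeric vectors plus `index_maps` mapping positions back to edge
#'   pairs / metric names / (metric, region) pairs.
#' @export
extract_features <- function(W, aucs) {
  n <- nrow(W)
  emap <- edge_index_map(n)
  regions <- rownames(W) %||% sprintf("R%03d", seq_len(n))
  connection <- upper_tri_vector(W)
  names(connection) <- paste(regions[emap$i], regions[emap$j], sep = "--")
  if (anyNA(connection)) stop("missing connection weights")
  global <- aucs$global[GLOBAL_METRIC_NAMES]
  if (anyNA(global)) {
    stop("missing global metric AUCs: ",
         paste(GLOBAL_METRIC_NAMES[is.na(global)], collapse = ", "))
  }
  nodal <- aucs$nodal
  if (length(nodal) != 5L * n) {
    stop("expected ", 5L * n, " nodal AUCs, got ", length(nodal))
  }
  if (anyNA(nodal)) {
    stop("missing nodal metric AUCs: ",
         paste(names(nodal)[is.na(nodal)], collapse = ", "))
  }
  nodal_map <- data.frame(
    metric = rep(NODAL_METRIC_NAMES, each = n),
    region = rep(regions, times = length(NODAL_METRIC_NAMES)))
  structure(
    list(connection = connection, global = global, nodal = nodal,
         index_maps = list(connection = cbind(emap, data.frame(
                             region_i = regions[emap$i],
                             region_j = regions[emap$j])),
                           global = GLOBAL_METRIC_NAMES,
                           nodal = nodal_map)),
    class = "feature_blocks")
}

#' Stack per-subject feature blocks into cohort matrices
#'
#' @param blocks_list list of `feature_blocks`, one per subject.
#' @return list of matrices (subjects x features) named `connection`,
#'   `global`, `nodal`, plus `index_maps` from the first subject.
#' @export
bind_feature_blocks <- function(blocks_list) {
  stopifnot(length(blocks_list) >= 1L)
  lens <- vapply(blocks_list, function(b) {
    c(length(b$connection), length(b$global), length(b$nodal))
  }, numeric(3L))
  if (any(lens != lens[, 1L])) {
    stop("inconsistent feature block lengths across subjects")
  }
  list(connection = do.call(rbind, lapply(blocks_list, `[[`, "connection")),
       global = do.call(rbind, lapply(blocks_list, `[[`, "global")),
       nodal = do.call(rbind, lapply(blocks_list, `[[`, "nodal")),
       index_maps = blocks_list[[1L]]$index_maps)
}

#' Fold-wise univariate t-test feature selection
#'
#' Two-sample two-tailed t-test per feature between classes, computed on
#' training subjects only; a feature is selected when p < alpha. Applied
#' independently within each block. If no feature in a block reaches
#' alpha, the single smallest-p feature is kept and the mask is flagged
#' (`fallback` attribute) so downstream kernels stay well-defined.
#'
#' @param train_blocks list of feature matrices (subjects x features) as
#'   from [bind_feature_blocks()] restricted to the training fold.
#' @param labels training labels in {+1, -1}.
#' @param alpha significance level (default 0.05).
#' @param blocks which blocks to select on (default all three).
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @param p_adjust `"none"` (default, the conventional uncorrected
#'   p < alpha rule) or `"BH"` for a Benjamini-Hochberg false-discovery
#'   threshold within each block.
#' @return object of class `selection_mask`: per-block list with logical
#'   `mask`, numeric `p`, and `fallback` flag.
#' @export
ttest_select <- function(train_blocks, labels, alpha = 0.05,
                         blocks = c("connection", "global", "nodal"),
                         var_equal = TRUE, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (length(unique(sign(labels))) < 2L) {
    stop("training labels contain a single class")
  }
  out <- lapply(blocks, function(b) {
    x <- train_blocks[[b]]
    tt <- col_ttest(x, labels, var_equal = var_equal)
    p_sel <- if (p_adjust == "BH") stats::p.adjust(tt$p, "BH") else tt$p
    mask <- p_sel < alpha
    fallback <- FALSE
    if (!any(mask)) {
      mask[which.min(tt$p)] <- TRUE
      fallback <- TRUE
    }
    list(mask = mask, t = tt$t, p = tt$p, mean_diff = tt$mean_diff,
         fallback = fallback)
  })
  names(out) <- blocks
  structure(out, alpha = alpha, class = "selection_mask")
}

#' Consensus connections across cross-validation folds
#'
#' Collects the connection features selected by the fold-wise filter over
#' the whole validation loop. The default consensus is the all-folds
#' intersection; the union and a per-edge selection-frequency table are
#' also returned. Each consensus edge is annotated with the sign of the
#' positive-class minus negative-class mean weight difference (computed
#' on the full cohort) and its largest p-value across folds; the most
#' significant connection is the one with the smallest maximum p.
#'
#' @param masks list of `selection_mask` objects, one per fold (>= 2).
#' @param index_map connection index map (from `feature_blocks$index_maps`).
#' @param cohort_diff optional full-cohort mean weight difference per
#'   connection feature (positive minus negative class), used for the
#'   direction annotation.
#' @return list with data.frames `intersection`, `union`, `frequency`.
#' @export
consensus_connections <- function(masks, index_map, cohort_diff = NULL) {
  if (length(masks) < 2L) stop("need at least 2 folds")
  mask_mat <- do.call(rbind, lapply(masks, function(m) m$connection$mask))
  p_mat <- do.call(rbind, lapply(masks, function(m) m$connection$p))
  freq <- colMeans(mask_mat)
  max_p <- apply(p_mat, 2L, max)
  direction <- if (is.null(cohort_diff)) rep(NA_character_, ncol(mask_mat)) else {
    ifelse(cohort_diff > 0, "increased", "decreased")
  }
  tab <- cbind(index_map,
               data.frame(frequency = freq, max_p = max_p,
                          direction = direction))
  inter <- tab[freq == 1, , drop = FALSE]
  union_tab <- tab[freq > 0, , drop = FALSE]
  if (nrow(inter) == 0L) {
    warning("empty consensus intersection; union still reported")
  }
  ord <- function(d) d[order(d$max_p, d$i, d$j), , drop = FALSE]
  list(intersection = ord(inter), union = ord(union_tab),
       frequency = tab[order(-tab$frequency, tab$max_p), , drop = FALSE])
}
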