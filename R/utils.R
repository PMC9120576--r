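# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
round_half_away <- function(x) {
  # round(), being banker's rounding, is grid-unstable at .5; edge counts
  # must round half away from zero.
  sign(x) * floor(abs(x) + 0.5)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Upper-triangle edge index map in row-major (i, j) order
#'
#' @param n number of regions.
#' @return data.frame with columns `i`, `j` (1-based, i < j), ordered
#'   lexicographically by (i, j). Row k is the k-th connection feature.
#' @keywords internal
#' @noRd
edge_index_map <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  data.frame(i = i, j = j)
}

#' Extract upper-triangle entries of a symmetric matrix in (i, j) order
#' @keywords internal
#' @noRd
upper_tri_vector <- function(M) {
  t(M)[lower.tri(M)]
}

#' Vectorized two-sample t-test over feature columns
#'
#' Pooled-variance Student t by default, Welch optionally. Columns with
#' zero pooled variance get p = 1 when the group means coincide and p = 0
#' when they differ (a zero-variance separated feature is infinitely
#' significant).
#'
#' @param x numeric matrix, subjects x features.
#' @param labels vector in {+1, -1}.
#' @param var_equal pooled (TRUE, default) or Welch (FALSE).
#' @return list with vectors `t`, `df`, `p`, `mean_diff` (positive-class
#'   mean minus negative-class mean).
#' @keywords internal
#' @noRd
col_ttest <- function(x, labels, var_equal = TRUE) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  pos <- labels > 0
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 < 2L || n2 < 2L) {
    stop("two-sample t-test needs at least 2 subjects per class (got ",
         n1, " and ", n2, ")")
  }
  m1 <- colMeans(x[pos, , drop = FALSE])
  m2 <- colMeans(x[!pos, , drop = FALSE])
  v1 <- apply(x[pos, , drop = FALSE], 2L, stats::var)
  v2 <- apply(x[!pos, , drop = FALSE], 2L, stats::var)
  d <- m1 - m2
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2, length(d))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- d / se
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- !is.finite(tt)
  if (any(zero)) {
    tt[zero] <- 0
    p[zero] <- ifelse(abs(d[zero]) > 0, 0, 1)
  }
  list(t = tt, df = df, p = p, mean_diff = d)
}
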