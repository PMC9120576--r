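#' Pearson-correlation functional brain network
#'
#' Estimates the subject's functional network as the matrix of Pearson
#' correlations between regional time series: each entry is the centered
#' dot product of two regional series normalized by the product of their
#' centered norms. The diagonal is set to exactly 1.
#'
#' @param series numeric matrix, timepoints x regions; column names are
#'   taken as region names.
#' @param subject_id optional subject identifier stored as an attribute.
#' @return symmetric correlation matrix (class `conn_matrix`) with unit
#'   diagonal and entries in \[-1, 1\].
#' @export
pearson_fbn <- function(series, subject_id = NULL) {
  if (!is.matrix(series) || !is.numeric(series)) {
    stop("series must be a numeric matrix (timepoints x regions)")
  }
  if (nrow(series) < 3L) stop("need at least 3 timepoints")
  if (anyNA(series)) stop("series contains missing values")
  v <- apply(series, 2L, stats::var)
  if (any(v == 0)) {
    bad <- colnames(series)[v == 0] %||% which(v == 0)
    stop("constant time series for region(s): ",
         paste(bad, collapse = ", "))
  }
  W <- stats::cor(series)
  W[W > 1] <- 1
  W[W < -1] <- -1
  W <- (W + t(W)) / 2
  diag(W) <- 1
  structure(W, class = c("conn_matrix", class(W)), subject_id = subject_id)
}

#' Proportional sparsity grid
#'
#' The grid of network densities at which each weighted network is
#' binarized. The default (0.02 to 0.50 in steps of 0.01) yields 49
#' thresholds.
#'
#' @param start,stop,step grid limits and spacing, all in (0, 1).
#' @return numeric vector of grid values, class `sparsity_grid` with a
#'   `step` attribute.
#' @export
sparsity_grid <- function(start = 0.02, stop = 0.50, step = 0.01) {
  if (!(start > 0 && start <= stop && stop < 1 && step > 0)) {
    stop("need 0 < start <= stop < 1 and step > 0")
  }
  k <- round((stop - start) / step)
  values <- start + step * (0:k)
  structure(values, step = step, class = "sparsity_grid")
}

#' Binarize a connectivity matrix at one proportional sparsity
#'
#' Retains the `m = round(s * n(n-1)/2)` strongest connections by signed
#' correlation value (largest first; rounding half away from zero). Ties
#' at the cut are broken by ascending lexicographic edge index, so the
#' result is deterministic. Set `absolute = TRUE` to rank by magnitude
#' instead.
#'
#' @param W connectivity matrix from [pearson_fbn()] (any symmetric
#'   numeric matrix works).
#' @param s sparsity in (0, 1): the fraction of possible edges kept.
#' @param absolute rank edges by |W| instead of signed value.
#' @return symmetric 0/1 adjacency matrix with zero diagonal.
#' @export
binarize_at_sparsity <- function(W, s, absolute = FALSE) {
  if (!(s > 0 && s < 1)) stop("sparsity must be in (0, 1)")
  n <- nrow(W)
  m_all <- n * (n - 1L) / 2L
  m <- round_half_away(s * m_all)
  if (m < 1L) stop("sparsity ", s, " keeps zero edges for n = ", n,
                   " (grid misconfiguration)")
  ord <- rank_edges(W, absolute)
  A <- matrix(0L, n, n, dimnames = dimnames(W))
  emap <- edge_index_map(n)
  keep <- ord[seq_len(m)]
  for (k in keep) {
    A[emap$i[k], emap$j[k]] <- 1L
    A[emap$j[k], emap$i[k]] <- 1L
  }
  A
}

#' @keywords internal
#' @noRd
rank_edges <- function(W, absolute = FALSE) {
  w <- upper_tri_vector(W)
  if (absolute) w <- abs(w)
  # decreasing by weight; order() is stable, and upper_tri_vector is in
  # ascending (i, j) lexicographic order, giving the documented tie-break
  order(-w)
}

#' Binarize across the whole sparsity grid
#'
#' Builds one adjacency per grid value from a single global edge ranking
#' with an increasing cut, so the stack is nested: the edge set at a
#' smaller sparsity is a subset of the edge set at any larger one.
#'
#' @inheritParams binarize_at_sparsity
#' @param grid a [sparsity_grid()].
#' @return object of class `graph_stack`: list with `thresholds`, `graphs`
#'   (list of adjacency matrices), `subject_id`.
#' @export
threshold_stack <- function(W, grid = sparsity_grid(), absolute = FALSE) {
  n <- nrow(W)
  m_all <- n * (n - 1L) / 2L
  ord <- rank_edges(W, absolute)
  emap <- edge_index_map(n)
  graphs <- vector("list", length(grid))
  A <- matrix(0L, n, n, dimnames = dimnames(W))
  m_prev <- 0L
  for (g in seq_along(grid)) {
    m <- round_half_away(grid[g] * m_all)
    if (m < 1L) stop("sparsity ", grid[g], " keeps zero edges for n = ", n)
    if (m > m_prev) {
      for (k in ord[(m_prev + 1L):m]) {
        A[emap$i[k], emap$j[k]] <- 1L
        A[emap$j[k], emap$i[k]] <- 1L
      }
      m_prev <- m
    }
    graphs[[g]] <- A
  }
  structure(list(thresholds = as.numeric(grid), graphs = graphs,
                 subject_id = attr(W, "subject_id")),
            class = "graph_stack")
}
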