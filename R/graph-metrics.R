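#' Global and nodal graph measurement names
#'
#' Fixed orderings used everywhere a metric vector is flattened into
#' features: 11 global measurements and 5 nodal (per-region) measurements.
#'
#' @format character vectors.
#' @name metric_names
NULL

#' @rdname metric_names
#' @export
GLOBAL_METRIC_NAMES <- c("Lp", "Cp", "lambda", "gamma", "sigma",
                         "Eglobal", "Elocal", "Q", "Ar", "Hr", "Sr")

#' @rdname metric_names
#' @export
NODAL_METRIC_NAMES <- c("degree", "efficiency", "betweenness",
                        "path_length", "clustering")

#' @keywords internal
#' @noRd
check_adjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("adjacency must be square")
  if (!all(A %in% c(0, 1))) stop("adjacency must be binary (0/1)")
  if (any(diag(A) != 0)) stop("adjacency must have a zero diagonal")
  if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE))) {
    stop("adjacency must be symmetric")
  }
  invisible(A)
}

#' @keywords internal
#' @noRd
as_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

#' Nodal (per-region) graph measurements of a binary graph
#'
#' Computes the five local measurements per node: degree centrality,
#' nodal efficiency (mean inverse distance to every other node, with
#' 1/Inf = 0), betweenness centrality (shortest-path pair dependencies
#' over unordered pairs, endpoints excluded), nodal shortest path length
#' (mean distance to reachable nodes, 0 for isolated nodes), and nodal
#' clustering coefficient (0 for degree < 2).
#'
#' @param A symmetric binary adjacency matrix with zero diagonal.
#' @return data.frame with one row per node and columns `degree`,
#'   `efficiency`, `betweenness`, `path_length`, `clustering`.
#' @export
nodal_metrics <- function(A) {
  check_adjacency(A)
  n <- nrow(A)
  g <- as_igraph(A)
  D <- igraph::distances(g)
  deg <- rowSums(A)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  invD <- 1 / D
  diag(invD) <- 0
  invD[is.infinite(D)] <- 0
  eff <- rowSums(invD) / (n - 1)
  Dfin <- D
  Dfin[is.infinite(Dfin)] <- NA
  diag(Dfin) <- NA
  spl <- rowMeans(Dfin, na.rm = TRUE)
  spl[is.nan(spl)] <- 0  # isolated node: no reachable peers
  btw <- igraph::betweenness(g, directed = FALSE)
  data.frame(degree = deg, efficiency = eff, betweenness = btw,
             path_length = spl, clustering = cc,
             row.names = rownames(A) %||% seq_len(n))
}

#' Configuration of the degree-preserving null model
#'
#' Null networks for the small-world normalizations are generated by
#' repeated double-edge swaps that preserve the exact degree sequence.
#'
#' @param n_nulls number of null networks per graph (default 100).
#' @param swaps_per_edge rewiring attempts per edge (default 10).
#' @param seed RNG seed for null generation.
#' @return object of class `null_model_config`.
#' @export
null_model_config <- function(n_nulls = 100L, swaps_per_edge = 10L,
                              seed = 1L) {
  if (n_nulls < 1L) stop("n_nulls must be >= 1")
  if (swaps_per_edge < 1L) stop("swaps_per_edge must be >= 1")
  structure(list(n_nulls = as.integer(n_nulls),
                 swaps_per_edge = as.integer(swaps_per_edge),
                 seed = as.integer(seed)),
            class = "null_model_config")
}

#' Degree-preserving rewired null networks
#'
#' Each null applies `swaps_per_edge * |E|` double-edge swap attempts,
#' preserving the degree sequence exactly. Deterministic given the seed.
#' Graphs admitting no valid swap (e.g. a star) yield nulls identical to
#' the input; the result is then flagged via the `degenerate` attribute.
#'
#' @param A symmetric binary adjacency matrix with zero diagonal.
#' @param nulls a [null_model_config()].
#' @return list of adjacency matrices with attribute `degenerate`.
#' @export
rewire_null <- function(A, nulls = null_model_config()) {
  check_adjacency(A)
  m <- sum(A) / 2
  if (m < 2) stop("need at least 2 edges to rewire")
  g <- as_igraph(A)
  niter <- nulls$swaps_per_edge * m
  out <- withr_seed(nulls$seed, {
    lapply(seq_len(nulls$n_nulls), function(k) {
      gk <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
      igraph::as_adjacency_matrix(gk, sparse = FALSE)
    })
  })
  degenerate <- all(vapply(out, function(Ak) all(Ak == A), logical(1L)))
  structure(out, degenerate = degenerate)
}

#' Global graph measurements of a binary graph
#'
#' Computes the 11 global measurements: clustering coefficient `Cp` (mean
#' nodal clustering, nodes of degree < 2 contributing 0), characteristic
#' path length `Lp` (mean distance over reachable unordered pairs),
#' normalized clustering `gamma` and path length `lambda` against
#' degree-preserving rewired nulls, small-world `sigma = gamma/lambda`,
#' global efficiency `Eglobal` (mean inverse distance over all unordered
#' pairs), local efficiency `Elocal` (mean over nodes of the global
#' efficiency of each node's open neighborhood subgraph), modularity `Q`
#' (greedy agglomerative optimization), assortativity `Ar` (Pearson
#' correlation of endpoint degrees over edges), hierarchy `Hr` (the
#' exponent beta of the power-law decline `log C_i = a - beta log k_i`
#' over nodes with degree >= 2 and positive clustering), and
#' synchronization `Sr` (Laplacian eigenratio lambda_2 / lambda_max).
#'
#' `Ar` is returned as `NA` for degree-regular graphs and `Hr` as `NA`
#' when fewer than 2 eligible nodes exist.
#'
#' @param A symmetric binary adjacency matrix with zero diagonal.
#' @param nulls a [null_model_config()]; used for `gamma`, `lambda`,
#'   `sigma`. Pass `NULL` to skip the null-normalized metrics (returned
#'   as `NA`).
#' @return named numeric vector over [GLOBAL_METRIC_NAMES].
#' @export
global_metrics <- function(A, nulls = null_model_config()) {
  check_adjacency(A)
  n <- nrow(A)
  if (sum(A) == 0) stop("empty graph: no measurements defined")
  g <- as_igraph(A)
  D <- igraph::distances(g)
  base <- cp_lp(g, D, n)
  Cp <- base[["Cp"]]; Lp <- base[["Lp"]]
  invD <- 1 / D
  diag(invD) <- 0
  invD[is.infinite(D)] <- 0
  Eglobal <- sum(invD) / (n * (n - 1))
  Elocal <- local_efficiency(A)
  Q <- igraph::modularity(g, igraph::membership(igraph::cluster_fast_greedy(g)))
  Ar <- degree_assortativity(A)
  Hr <- hierarchy_exponent(A, g)
  Sr <- laplacian_eigenratio(A)
  gamma <- lambda <- sigma <- NA_real_
  if (!is.null(nulls) && sum(A) / 2 >= 2) {
    null_graphs <- rewire_null(A, nulls)
    null_cl <- vapply(null_graphs, function(Ak) {
      gk <- as_igraph(Ak)
      cp_lp(gk, igraph::distances(gk), n)
    }, numeric(2L))
    mean_null_cp <- mean(null_cl[1L, ])
    mean_null_lp <- mean(null_cl[2L, ])
    gamma <- if (mean_null_cp > 0) Cp / mean_null_cp else NA_real_
    lambda <- if (mean_null_lp > 0) Lp / mean_null_lp else NA_real_
    sigma <- if (is.finite(gamma) && is.finite(lambda) && lambda != 0) {
      gamma / lambda
    } else NA_real_
  }
  c(Lp = Lp, Cp = Cp, lambda = lambda, gamma = gamma, sigma = sigma,
    Eglobal = Eglobal, Elocal = Elocal, Q = Q, Ar = Ar, Hr = Hr, Sr = Sr)
}

#' @keywords internal
#' @noRd
cp_lp <- function(g, D, n) {
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  fin <- is.finite(D) & upper.tri(D)
  Lp <- if (any(fin)) mean(D[fin]) else NA_real_
  c(Cp = mean(cc), Lp = Lp)
}

#' @keywords internal
#' @noRd
local_efficiency <- function(A) {
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2L) return(0)
    sub <- A[nb, nb, drop = FALSE]
    if (sum(sub) == 0) return(0)
    Ds <- igraph::distances(as_igraph(sub))
    inv <- 1 / Ds
    diag(inv) <- 0
    inv[is.infinite(Ds)] <- 0
    sum(inv) / (k * (k - 1))
  }, numeric(1L))
  mean(vals)
}

#' @keywords internal
#' @noRd
degree_assortativity <- function(A) {
  deg <- rowSums(A)
  idx <- which(A == 1 & upper.tri(A), arr.ind = TRUE)
  x <- deg[idx[, 1L]]; y <- deg[idx[, 2L]]
  # Newman's r: Pearson correlation of endpoint degrees over the doubled
  # (both orientations) edge list
  xs <- c(x, y); ys <- c(y, x)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)
}

#' @keywords internal
#' @noRd
hierarchy_exponent <- function(A, g) {
  deg <- rowSums(A)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  ok <- deg >= 2 & cc > 0
  if (sum(ok) < 2L) return(NA_real_)
  lk <- log(deg[ok]); lc <- log(cc[ok])
  if (stats::sd(lk) == 0) return(NA_real_)
  slope <- stats::cov(lk, lc) / stats::var(lk)
  -slope
}

#' @keywords internal
#' @noRd
laplacian_eigenratio <- function(A) {
  deg <- rowSums(A)
  L <- diag(deg) - A
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  lam_max <- ev[1L]
  lam2 <- ev[length(ev) - 1L]
  if (lam_max <= 0) return(NA_real_)
  lam2 / lam_max
}

#' Aggregate per-threshold metric values into an area-under-curve feature
#'
#' The default `sum` mode returns the plain sum of the per-threshold
#' values (so a constant-1 metric over 49 thresholds gives 49); the
#' `step` mode multiplies by the grid step, giving a rectangle-rule
#' integral over sparsity.
#'
#' @param values numeric vector, one value per grid point.
#' @param grid the [sparsity_grid()] the values were computed on.
#' @param mode `"sum"` (default) or `"step"`.
#' @return scalar with attribute `mode`.
#' @export
auc_over_thresholds <- function(values, grid, mode = c("sum", "step")) {
  mode <- match.arg(mode)
  if (length(values) != length(grid)) {
    stop("got ", length(values), " values for a grid of length ",
         length(grid))
  }
  if (anyNA(values)) stop("missing metric values in threshold curve")
  out <- sum(values)
  if (mode == "step") out <- out * attr(grid, "step")
  structure(out, mode = mode)
}

#' All graph measurements of one subject across a threshold stack
#'
#' @param stack a `graph_stack` from [threshold_stack()].
#' @param nulls a [null_model_config()] (or NULL to skip gamma/lambda/sigma).
#' @return list with `global` (thresholds x 11 matrix) and `nodal`
#'   (3-d array: thresholds x 5 metrics x regions).
#' @export
stack_metrics <- function(stack, nulls = null_model_config()) {
  stopifnot(inherits(stack, "graph_stack"))
  n_thr <- length(stack$thresholds)
  n <- nrow(stack$graphs[[1L]])
  glob <- matrix(NA_real_, n_thr, length(GLOBAL_METRIC_NAMES),
                 dimnames = list(NULL, GLOBAL_METRIC_NAMES))
  nod <- array(NA_real_, dim = c(n_thr, length(NODAL_METRIC_NAMES), n),
               dimnames = list(NULL, NODAL_METRIC_NAMES,
                               rownames(stack$graphs[[1L]])))
  for (t in seq_len(n_thr)) {
    A <- stack$graphs[[t]]
    nulls_t <- if (is.null(nulls)) NULL else {
      null_model_config(nulls$n_nulls, nulls$swaps_per_edge,
                        seed = nulls$seed + t)
    }
    glob[t, ] <- global_metrics(A, nulls_t)
    nm <- nodal_metrics(A)
    for (m in seq_along(NODAL_METRIC_NAMES)) {
      nod[t, m, ] <- nm[[NODAL_METRIC_NAMES[m]]]
    }
  }
  list(global = glob, nodal = nod)
}

#' Collapse stack metrics to AUC features
#'
#' @param metrics output of [stack_metrics()].
#' @param grid the grid the stack was built on.
#' @param mode AUC mode, see [auc_over_thresholds()].
#' @param na_action `"error"` (default) rejects missing per-threshold
#'   values; `"omit"` sums over the non-missing thresholds (the count of
#'   omitted values is recorded in attribute `n_omitted`).
#' @return list with `global` (named 11-vector) and `nodal` (named
#'   5 x n_regions vector, metric-major).
#' @export
metric_aucs <- function(metrics, grid, mode = c("sum", "step"),
                        na_action = c("error", "omit")) {
  mode <- match.arg(mode)
  na_action <- match.arg(na_action)
  step <- attr(grid, "step")
  agg <- function(v) {
    n_miss <- sum(is.na(v))
    if (n_miss > 0L && na_action == "error") {
      stop("missing metric values in threshold curve")
    }
    s <- sum(v, na.rm = TRUE)
    if (mode == "step") s <- s * step
    s
  }
  glob <- vapply(seq_len(ncol(metrics$global)),
                 function(m) agg(metrics$global[, m]), numeric(1L))
  names(glob) <- colnames(metrics$global)
  n <- dim(metrics$nodal)[3L]
  regions <- dimnames(metrics$nodal)[[3L]] %||% seq_len(n)
  nodal <- numeric(0)
  for (m in seq_along(NODAL_METRIC_NAMES)) {
    v <- vapply(seq_len(n), function(r) agg(metrics$nodal[, m, r]),
                numeric(1L))
    names(v) <- paste(NODAL_METRIC_NAMES[m], regions, sep = ".")
    nodal <- c(nodal, v)
  }
  n_omitted <- sum(is.na(metrics$global)) + sum(is.na(metrics$nodal))
  structure(list(global = glob, nodal = nodal),
            mode = mode, n_omitted = if (na_action == "omit") n_omitted else 0L)
}
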