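#' Specify a synthetic two-group cohort
#'
#' Defines a two-group cohort of regional time series whose population
#' correlation matrices differ on a planted set of edges. Defaults mirror a
#' 92-subject resting-state cohort: 90 regions, 170 retained timepoints,
#' 45 positive-class and 47 negative-class subjects.
#'
#' @param n_regions number of regions (network nodes), >= 3.
#' @param n_timepoints series length, >= 10.
#' @param n_group_pos,n_group_neg subjects per group (positive class is
#'   labeled +1, negative -1).
#' @param planted_edges two-column matrix (or list of pairs) of 1-based
#'   region indices; the population correlation on these edges differs
#'   between groups.
#' @param effect_size shift in population correlation applied to the
#'   positive group on the planted edges (before positive-definite repair).
#' @param base_density fraction of off-diagonal entries carrying shared
#'   base correlation structure (common to both groups).
#' @param noise_sd standard deviation of additive iid Gaussian observation
#'   noise on the series; attenuates all sample correlations uniformly.
#' @param seed integer; generation is a pure function of the spec
#'   including this seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_regions = 90L, n_timepoints = 170L,
                        n_group_pos = 45L, n_group_neg = 47L,
                        planted_edges = NULL, effect_size = 0,
                        base_density = 0.15, noise_sd = 0.3,
                        seed = 1L) {
  if (n_regions < 3L) stop("n_regions must be >= 3")
  if (n_timepoints < 10L) stop("n_timepoints must be >= 10")
  if (n_group_pos < 1L || n_group_neg < 1L) {
    stop("each group needs at least one subject")
  }
  if (base_density < 0 || base_density >= 1) {
    stop("base_density must be in [0, 1)")
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  pe <- normalize_planted_edges(planted_edges, n_regions)
  spec <- structure(
    list(n_regions = as.integer(n_regions),
         n_timepoints = as.integer(n_timepoints),
         n_group_pos = as.integer(n_group_pos),
         n_group_neg = as.integer(n_group_neg),
         planted_edges = pe,
         effect_size = effect_size,
         base_density = base_density,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec")
  spec
}

#' @keywords internal
#' @noRd
normalize_planted_edges <- function(planted_edges, n_regions) {
  if (is.null(planted_edges) || length(planted_edges) == 0L) {
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  }
  if (is.list(planted_edges)) {
    planted_edges <- do.call(rbind, lapply(planted_edges, as.integer))
  }
  pe <- matrix(as.integer(planted_edges), ncol = 2L)
  if (any(pe < 1L) || any(pe > n_regions)) {
    stop("planted edge endpoints must lie in [1, n_regions]")
  }
  if (any(pe[, 1L] == pe[, 2L])) {
    stop("planted edges must have distinct endpoints")
  }
  pe <- cbind(i = pmin(pe[, 1L], pe[, 2L]), j = pmax(pe[, 1L], pe[, 2L]))
  if (anyDuplicated(pe)) stop("duplicated planted edges")
  pe
}

#' Population correlation targets for the two groups
#'
#' Builds the shared base correlation structure (random sparse symmetric
#' entries at `base_density` with magnitudes in \[0.2, 0.5\]), plants the
#' group difference, then repairs each matrix to positive definiteness by
#' eigenvalue flooring and re-normalization to unit diagonal.
#'
#' @param spec a [cohort_spec()].
#' @return list with `R_neg` and `R_pos`, both symmetric, unit-diagonal,
#'   positive-definite correlation matrices.
#' @export
build_group_correlation_targets <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_regions
  base <- withr_seed(spec$seed, {
    B <- diag(n)
    m_all <- n * (n - 1L) / 2L
    m_base <- round_half_away(spec$base_density * m_all)
    if (m_base > 0L) {
      emap <- edge_index_map(n)
      pick <- sample.int(m_all, m_base)
      w <- stats::runif(m_base, 0.2, 0.5) *
        sample(c(-1, 1), m_base, replace = TRUE)
      for (k in seq_len(m_base)) {
        i <- emap$i[pick[k]]; j <- emap$j[pick[k]]
        B[i, j] <- B[j, i] <- w[k]
      }
    }
    B
  })
  R_neg_raw <- base
  R_pos_raw <- base
  pe <- spec$planted_edges
  for (k in seq_len(nrow(pe))) {
    i <- pe[k, 1L]; j <- pe[k, 2L]
    target <- R_pos_raw[i, j] + spec$effect_size
    if (target <= -1 || target >= 1) {
      stop(sprintf(
        "effect_size pushes correlation of edge (%d, %d) to %.3f, outside (-1, 1)",
        i, j, target))
    }
    R_pos_raw[i, j] <- R_pos_raw[j, i] <- target
  }
  list(R_neg = pd_repair(R_neg_raw), R_pos = pd_repair(R_pos_raw))
}

#' Eigenvalue-floor positive-definite repair with unit-diagonal rescale
#' @keywords internal
#' @noRd
pd_repair <- function(M, floor = 1e-6, max_iter = 50L) {
  for (it in seq_len(max_iter)) {
    e <- eigen(M, symmetric = TRUE)
    if (min(e$values) >= floor) return(M)
    # floor with headroom: re-normalization to unit diagonal shrinks the
    # smallest eigenvalue slightly, so flooring exactly at the target
    # oscillates just below it
    vals <- pmax(e$values, 10 * floor)
    M <- e$vectors %*% (vals * t(e$vectors))
    d <- sqrt(diag(M))
    M <- M / tcrossprod(d)
    M <- (M + t(M)) / 2
    diag(M) <- 1
  }
  stop("positive-definite repair did not converge")
}

#' Evaluate an expression under a temporary RNG state
#' @keywords internal
#' @noRd
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a two-group cohort of regional time series
#'
#' Each subject's series is drawn independently from a zero-mean
#' multivariate normal with its group's target correlation matrix, plus
#' independent Gaussian noise of sd `noise_sd`. Generation is a pure
#' function of the spec (including its seed).
#'
#' @param spec a [cohort_spec()].
#' @return object of class `ts_cohort`: list with `subjects` (list of
#'   timepoints x regions matrices), `subject_ids`, `labels` (+1/-1
#'   vector), `region_names`, and the generating `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  targets <- build_group_correlation_targets(spec)
  n <- spec$n_regions
  t_len <- spec$n_timepoints
  region_names <- sprintf("R%03d", seq_len(n))
  n_tot <- spec$n_group_pos + spec$n_group_neg
  labels <- c(rep.int(1L, spec$n_group_pos), rep.int(-1L, spec$n_group_neg))
  chol_pos <- chol(targets$R_pos)
  chol_neg <- chol(targets$R_neg)
  subjects <- withr_seed(spec$seed + 1L, {
    lapply(seq_len(n_tot), function(s) {
      L <- if (labels[s] > 0) chol_pos else chol_neg
      X <- matrix(stats::rnorm(t_len * n), t_len, n) %*% L
      if (spec$noise_sd > 0) {
        X <- X + spec$noise_sd * matrix(stats::rnorm(t_len * n), t_len, n)
      }
      colnames(X) <- region_names
      v <- apply(X, 2L, stats::var)
      if (any(v == 0)) stop("degenerate simulation: zero-variance region")
      X
    })
  })
  structure(
    list(subjects = subjects,
         subject_ids = sprintf("sub-%03d", seq_len(n_tot)),
         labels = labels,
         region_names = region_names,
         spec = spec),
    class = "ts_cohort")
}

#' @export
print.ts_cohort <- function(x, ...) {
  cat(sprintf(
    "<ts_cohort> %d subjects (%d positive, %d negative), %d regions, %d timepoints\n",
    length(x$subjects), sum(x$labels > 0), sum(x$labels < 0),
    length(x$region_names), nrow(x$subjects[[1L]])))
  invisible(x)
}

#' Write a cohort to disk as per-subject TSV files plus a manifest
#'
#' One tab-delimited file per subject (rows = timepoints, columns =
#' regions, header row of region names) and a `manifest.csv` with columns
#' `subject_id,path,label`. Round-trips through [read_cohort()].
#'
#' @param cohort a `ts_cohort`.
#' @param directory output directory (created if needed).
#' @param overwrite overwrite an existing manifest? Default FALSE.
#' @return path to the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, directory, overwrite = FALSE) {
  stopifnot(inherits(cohort, "ts_cohort"))
  if (length(cohort$subjects) == 0L) stop("refusing to write an empty cohort")
  manifest_path <- file.path(directory, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite) {
    stop("manifest already exists at ", manifest_path,
         " (use overwrite = TRUE)")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  rel_paths <- paste0(cohort$subject_ids, ".tsv")
  for (s in seq_along(cohort$subjects)) {
    utils::write.table(
      cohort$subjects[[s]], file.path(directory, rel_paths[s]),
      sep = "\t", row.names = FALSE, col.names = TRUE, quote = FALSE)
  }
  manifest <- data.frame(subject_id = cohort$subject_ids,
                         path = rel_paths,
                         label = cohort$labels)
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}
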