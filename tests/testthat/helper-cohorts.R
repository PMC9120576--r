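# Small cohort fixtures built in code.

tiny_spec <- function(seed = 1, effect = 0, n_regions = 12,
                      n_timepoints = 60, n_pos = 8, n_neg = 8,
                      planted = NULL, noise_sd = 0.3) {
  cohort_spec(n_regions = n_regions, n_timepoints = n_timepoints,
              n_group_pos = n_pos, n_group_neg = n_neg,
              planted_edges = planted, effect_size = effect,
              base_density = 0.15, noise_sd = noise_sd, seed = seed)
}

# Connection-only feature matrices straight from the correlation matrices
# (skips graph metrics; used where only the connection block matters).
connection_features <- function(cohort) {
  mats <- lapply(cohort$subjects, pearson_fbn)
  X <- do.call(rbind, lapply(mats, function(W) t(W)[lower.tri(W)]))
  n <- length(cohort$region_names)
  map <- data.frame(
    i = rep.int(seq_len(n - 1L), (n - 1L):1L),
    j = unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n)))
  list(connection = X, map = map, labels = cohort$labels)
}

# A fast pipeline configuration for desk-scale tests: coarse sparsity
# grid over the density range where small random networks keep all
# measurements defined, few nulls, reduced hyperparameter grid.
fast_config <- function(methods = c("C", "G", "N", "C+G+N"), seed = 1) {
  pipeline_config(
    grid = sparsity_grid(0.20, 0.44, 0.04),
    nulls = null_model_config(n_nulls = 2, swaps_per_edge = 5, seed = seed),
    hyper = hyper_grid(C_values = 2^c(-3, 0, 3), beta_step = 0.5),
    methods = methods, inner_k = 3, na_action = "omit", seed = seed)
}
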