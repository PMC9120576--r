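# Shared study configuration for the analysis scripts.
#
# The cohort is a desk-scale synthetic analogue of a two-group
# resting-state study: 24 subjects (12 per group), 16 regions, short
# noisy series, with a clique of elevated correlations planted among
# regions 1-8 in the positive group so that connection weights, global
# topology, and nodal topology each carry partial signal.

library(fbnclass)

study_seed <- 42L

study_spec <- cohort_spec(
  n_regions = 16, n_timepoints = 30,
  n_group_pos = 12, n_group_neg = 12,
  planted_edges = t(combn(1:8, 2)),
  effect_size = 0.22, base_density = 0.15, noise_sd = 0.3,
  seed = study_seed)

study_config <- pipeline_config(
  grid = sparsity_grid(0.14, 0.44, 0.02),
  nulls = null_model_config(n_nulls = 2, swaps_per_edge = 5,
                            seed = study_seed),
  hyper = hyper_grid(C_values = 2^c(-3, 0, 3), beta_step = 0.5),
  methods = names(method_configs()),
  inner_k = 5L, na_action = "omit", seed = study_seed)

results_dir <- "results"
cohort_dir <- file.path(results_dir, "cohort")
dir.create(results_dir, showWarnings = FALSE)
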