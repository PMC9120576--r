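# Group-level descriptive analyses: hub regions of the mean networks and
# between-group comparisons of nodal degree and betweenness AUC features.

source("analysis/00_config.R")

cohort <- read_cohort(file.path(cohort_dir, "manifest.csv"))
prep <- cohort_features(cohort, study_config)

nodal_map <- prep$features$index_maps$nodal
deg_cols <- which(nodal_map$metric == "degree")
btw_cols <- which(nodal_map$metric == "betweenness")

deg <- prep$features$nodal[, deg_cols, drop = FALSE]
colnames(deg) <- nodal_map$region[deg_cols]
btw <- prep$features$nodal[, btw_cols, drop = FALSE]
colnames(btw) <- nodal_map$region[btw_cols]

cat("regions with significant degree differences:\n")
cmp_deg <- compare_group_metrics(deg, cohort$labels)
print(subset(cmp_deg, significant), row.names = FALSE, digits = 3)
write.csv(cmp_deg, file.path(results_dir, "group_degree.csv"),
          row.names = FALSE)

cat("\nregions with significant betweenness differences:\n")
cmp_btw <- compare_group_metrics(btw, cohort$labels)
print(subset(cmp_btw, significant), row.names = FALSE, digits = 3)
write.csv(cmp_btw, file.path(results_dir, "group_betweenness.csv"),
          row.names = FALSE)

# hubs of the positive-group mean network at the 5% and 20% rules
nets <- group_mean_network(lapply(cohort$subjects, pearson_fbn),
                           cohort$labels)
for (pr in c(0.05, 0.20)) {
  hubs <- hub_nodes(nets$pos, proportion = pr, measure = "strength")
  cat(sprintf("\ntop %d%% strength hubs (positive group): %s\n",
              round(100 * pr), paste(hubs$region, collapse = ", ")))
  write.csv(hubs, file.path(results_dir,
                            sprintf("hubs_pos_p%02d.csv", 100 * pr)),
            row.names = FALSE)
}
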