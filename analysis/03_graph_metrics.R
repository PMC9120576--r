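# Compute the global and nodal graph measurements over the sparsity
# grid, collapse them to AUC features, and write the per-subject feature
# matrices used by the classification and group-analysis steps.

source("analysis/00_config.R")

cohort <- read_cohort(file.path(cohort_dir, "manifest.csv"))
prep <- cohort_features(cohort, study_config)

write.csv(cbind(subject = cohort$subject_ids, label = cohort$labels,
                as.data.frame(prep$features$connection)),
          file.path(results_dir, "features_connection.csv"),
          row.names = FALSE)
write.csv(cbind(subject = cohort$subject_ids, label = cohort$labels,
                as.data.frame(prep$features$global)),
          file.path(results_dir, "features_global.csv"), row.names = FALSE)
write.csv(cbind(subject = cohort$subject_ids, label = cohort$labels,
                as.data.frame(prep$features$nodal)),
          file.path(results_dir, "features_nodal.csv"), row.names = FALSE)
cat("feature blocks:",
    ncol(prep$features$connection), "connection,",
    ncol(prep$features$global), "global,",
    ncol(prep$features$nodal), "nodal\n")

# group contrast of the global measurements (AUC over the grid)
cmp <- compare_group_metrics(prep$features$global, cohort$labels)
print(cmp, row.names = FALSE, digits = 3)
write.csv(cmp, file.path(results_dir, "group_global_metrics.csv"),
          row.names = FALSE)
cat("significant global measurements at p < 0.05:",
    paste(cmp$feature[cmp$significant], collapse = ", "), "\n")
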