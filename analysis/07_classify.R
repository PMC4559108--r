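#!/usr/bin/env Rscript
# Stage 7: robust selection and bacterial-vs-chemical classification.
#
# Combines the correlation records of both experiments: a metabolite is
# robust when its RT correlation replicates (same significance and sign)
# across experiments and its 4 degrees C status is concordant. Robust
# metabolites significant only at RT are attributed to bacterial
# overgrowth; those also significant at 4 degrees C and/or with
# preservative to chemical instability. The calls are finally compared
# against the generator's ground-truth ledger.

library(urostab)

uni_dir <- "results/05_univariate"
ann_dir <- "results/04_annotation"
sim_dir <- "results/01_simulated"
out_dir <- "results/07_classification"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

records <- read_results(file.path(uni_dir, "correlation_records.tsv"))
onsets <- read_results(file.path(uni_dir, "onset_times.tsv"))
calls <- classify_calls(records, onsets)

ann <- read_results(file.path(ann_dir, "annotations.tsv"))
best <- ann[ann$rank == 1, c("feature_id", "name", "msi_level")]
best <- best[!duplicated(best$feature_id), ]
calls <- merge(calls, best, by = "feature_id", all.x = TRUE, sort = FALSE)

s <- summarize_calls(calls, records)
write_results(calls, file.path(out_dir, "stability_calls.tsv"))
write_results(s$class_counts, file.path(out_dir, "class_counts.tsv"))
write_results(s$experiment_counts,
              file.path(out_dir, "experiment_counts.tsv"))

message("stability calls:")
for (i in seq_len(nrow(s$class_counts))) {
  message(sprintf("  %-25s %d", s$class_counts$class[i], s$class_counts$n[i]))
}

truth <- read_results(file.path(sim_dir, "ground_truth_features.tsv"))
planted <- truth[truth$class != "stable", ]
got <- calls$class[match(planted$feature_id, calls$feature_id)]
correct <- !is.na(got) & got == planted$class
false_unstable <- setdiff(
  calls$feature_id[calls$class %in% c("bacterial", "chemical")],
  planted$feature_id)
message(sprintf(
  "ground-truth check: %d/%d planted metabolites correctly classed; %d false unstable call(s)",
  sum(correct), nrow(planted), length(false_unstable)))
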