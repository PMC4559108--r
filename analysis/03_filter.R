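#!/usr/bin/env Rscript
# Stage 3: feature and observation filtering.
#
# Removes features still correlated with injection order after drift
# correction (BH q < 0.05), features whose QC mean does not exceed twice
# the blank mean (on raw intensities), features with QC CV > 30 %, and
# study injections with outlying intensity-distribution quantiles
# (p < 1e-3 against the other injections of the same condition).

library(urostab)

raw_dir <- "results/01_simulated"
in_dir <- "results/02_normalized"
out_dir <- "results/03_filtered"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

keys <- sub("_intensities\\.tsv$", "",
            list.files(in_dir, pattern = "_intensities\\.tsv$"))
for (k in keys) {
  norm <- read_feature_table(file.path(in_dir, paste0(k, "_intensities.tsv")),
                             file.path(in_dir, paste0(k, "_injections.tsv")))
  raw <- read_feature_table(file.path(raw_dir, paste0(k, "_intensities.tsv")),
                            file.path(raw_dir, paste0(k, "_injections.tsv")))

  iof <- injection_order_filter(norm, alpha = 0.05)
  bf <- blank_filter(iof$table, ratio_min = 2,
                     raw = ft_subset(raw,
                                     features = iof$table$features$feature_id))
  cf <- cv_filter(bf$table, cv_max = 0.30)
  ol <- detect_outlier_observations(cf$table, p_threshold = 1e-3)

  message(sprintf(
    "%s: %d -> %d features (order %d, blank %d, CV %d); %d outlier injection(s): %s",
    k, nrow(norm$intensities), nrow(ol$table$intensities),
    length(iof$discarded), sum(!bf$report$pass), sum(!cf$report$pass),
    length(ol$removed),
    if (length(ol$removed)) paste(ol$removed, collapse = ", ") else "none"))

  write_results(iof$report, file.path(out_dir, paste0(k, "_order_filter.tsv")))
  write_results(bf$report, file.path(out_dir, paste0(k, "_blank_filter.tsv")))
  write_results(cf$report, file.path(out_dir, paste0(k, "_cv_filter.tsv")))
  write_results(ol$report, file.path(out_dir, paste0(k, "_outliers.tsv")))
  write_feature_table(ol$table,
                      file.path(out_dir, paste0(k, "_intensities.tsv")),
                      file.path(out_dir, paste0(k, "_injections.tsv")))
}
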