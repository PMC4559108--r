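#!/usr/bin/env Rscript
# Stage 5: per-condition Spearman screen and onset times.
#
# Each feature's intensity is correlated with storage duration within
# each condition (replicates pooled), with BH control at FDR 0.01 across
# the features of each block x condition. For every significant trend
# the onset time is the first time point whose triplicates all lie
# beyond the full T0 replicate range in the trend direction.

library(urostab)

in_dir <- "results/03_filtered"
out_dir <- "results/05_univariate"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

keys <- sub("_intensities\\.tsv$", "",
            list.files(in_dir, pattern = "_intensities\\.tsv$"))
records <- list()
onsets <- list()
for (k in keys) {
  tab <- read_feature_table(file.path(in_dir, paste0(k, "_intensities.tsv")),
                            file.path(in_dir, paste0(k, "_injections.tsv")))
  recs <- screen_conditions(tab, alpha = 0.01)
  ons <- onset_table(tab, recs)
  records[[k]] <- recs
  onsets[[k]] <- ons
  sig <- recs[recs$significant, ]
  message(sprintf("%s: %d significant feature x condition trends (%s)",
                  k, nrow(sig),
                  paste(sprintf("%s: %d", names(table(sig$condition)),
                                table(sig$condition)), collapse = ", ")))
}
write_results(do.call(rbind, records),
              file.path(out_dir, "correlation_records.tsv"))
write_results(do.call(rbind, onsets), file.path(out_dir, "onset_times.tsv"))
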