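#!/usr/bin/env Rscript
# Stage 4: metabolite annotation.
#
# Matches the filtered features against the demonstration spectral
# library by accurate mass (5 ppm) and retention time (0.5 min),
# carrying MSI identification levels. The shipped library is synthetic:
# Table-2-style metabolite names with approximate ion masses and
# invented retention times.

library(urostab)

in_dir <- "results/03_filtered"
out_dir <- "results/04_annotation"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

lib <- demo_library()
keys <- sub("_intensities\\.tsv$", "",
            list.files(in_dir, pattern = "_intensities\\.tsv$"))
all_hits <- list()
for (k in keys) {
  tab <- read_feature_table(file.path(in_dir, paste0(k, "_intensities.tsv")),
                            file.path(in_dir, paste0(k, "_injections.tsv")))
  hits <- annotate(tab, lib, ppm_tol = 5, rt_tol_min = 0.5)
  all_hits[[k]] <- if (nrow(hits)) cbind(block = k, hits) else NULL
  message(sprintf("%s: %d of %d features annotated (%d library hits)",
                  k, length(unique(hits$feature_id)),
                  nrow(tab$intensities), nrow(hits)))
}
write_results(do.call(rbind, all_hits),
              file.path(out_dir, "annotations.tsv"))
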