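#!/usr/bin/env Rscript
# Stage 6: multivariate overview and PLS modelling of storage duration.
#
# Per block: log10 / centre / unit-variance preprocessing, PCA for an
# overview of the variability, a two-component PLS with storage duration
# as the response, venetian-blind cross-validated Q2, a 999-permutation
# significance test, VIP scores and their concordance with the
# room-temperature univariate p-values.

library(urostab)

in_dir <- "results/03_filtered"
uni_dir <- "results/05_univariate"
out_dir <- "results/06_multivariate"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

recs_all <- read_results(file.path(uni_dir, "correlation_records.tsv"))
keys <- sub("_intensities\\.tsv$", "",
            list.files(in_dir, pattern = "_intensities\\.tsv$"))
summary_rows <- list()
for (k in keys) {
  tab <- read_feature_table(file.path(in_dir, paste0(k, "_intensities.tsv")),
                            file.path(in_dir, paste0(k, "_injections.tsv")))
  pm <- preprocess(tab)
  y <- pm$obs_meta$time_h
  pc <- pca(pm, n_comp = 2)
  fit <- pls(pm, y, n_comp = 2)
  perm <- permutation_test(pm, y, n_comp = 2, n_perm = 999, n_folds = 7,
                           seed = 20141223)
  v <- vip(fit)

  rt <- recs_all[recs_all$condition == "RT" &
                   paste(rt_exp <- recs_all$experiment,
                         recs_all$ion_mode, sep = ".") == k, ]
  kk <- sum(rt$significant)
  conc <- if (kk >= 1) {
    idx <- match(rt$feature_id, pm$var_id)
    ok <- !is.na(idx)
    vip_pvalue_concordance(v[idx[ok]], rt$p[ok], k = min(kk, sum(ok)))
  } else NA_real_

  scores <- data.frame(injection_id = pm$obs_id, pm$obs_meta[
    c("condition", "time_h", "replicate")],
    pc1 = pc$scores[, 1], pc2 = pc$scores[, 2],
    pls_t1 = fit$scores[, 1], pls_t2 = fit$scores[, 2])
  write_results(scores, file.path(out_dir, paste0(k, "_scores.tsv")))
  write_results(data.frame(feature_id = names(v), vip = unname(v)),
                file.path(out_dir, paste0(k, "_vip.tsv")))

  message(sprintf(
    "%s: PCA ExpX %.0f%%+%.0f%%; PLS ExpY %.0f%%, Q2 = %.2f, perm p = %.3g, VIP/p concordance %.0f%%",
    k, 100 * pc$explained[1], 100 * pc$explained[2],
    100 * fit$expl_y[2], perm$q2_obs, perm$p, 100 * conc))
  summary_rows[[k]] <- data.frame(
    block = k, expx1 = pc$explained[1], expx2 = pc$explained[2],
    expy = fit$expl_y[2], q2 = perm$q2_obs, perm_p = perm$p,
    vip_p_concordance = conc)
}
write_results(do.call(rbind, summary_rows),
              file.path(out_dir, "model_summary.tsv"))
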