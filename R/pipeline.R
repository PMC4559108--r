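#' Pipeline configuration
#'
#' Assembles and validates every stage parameter of the end-to-end
#' workflow before any stage runs. The pipeline consumes either a
#' simulation configuration (`sim`) or pre-loaded raw feature tables
#' (`tables`, one per experiment x ion-mode block).
#'
#' @param sim a [sim_config()] (ignored when `tables` is given).
#' @param tables named list of raw [feature_table()] blocks.
#' @param span,degree,fallback drift-correction parameters (see
#'   [loess_drift_correct()]).
#' @param scale_mode block-scaling mode (see [block_scale()]).
#' @param order_alpha BH threshold of the injection-order filter.
#' @param blank_ratio,cv_max,outlier_p filtering parameters.
#' @param ppm_tol,rt_tol_min,library annotation parameters.
#' @param alpha FDR threshold of the univariate screen.
#' @param n_comp,n_folds,n_perm multivariate parameters.
#' @param run_multivariate set `FALSE` to skip PCA/PLS (e.g. when only
#'   stability calls are needed).
#' @param allow_list feature ids force-included in the selection.
#' @param seed seed for the stochastic stages (permutation test).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, tables = NULL,
                            span = 0.75, degree = 2, fallback = "auto",
                            scale_mode = "common",
                            order_alpha = 0.05,
                            blank_ratio = 2, cv_max = 0.30,
                            outlier_p = 1e-3,
                            ppm_tol = 5, rt_tol_min = 0.5,
                            library = demo_library(),
                            alpha = 0.01,
                            n_comp = 2, n_folds = 7, n_perm = 1000,
                            run_multivariate = TRUE,
                            allow_list = character(0),
                            seed = 1) {
  if (is.null(sim) && is.null(tables)) {
    stop("provide either `sim` or `tables`")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (!is.null(tables)) {
    stopifnot(is.list(tables), length(tables) >= 1)
    lapply(tables, function(b) stopifnot(inherits(b, "feature_table")))
  }
  stopifnot(span > 0, span <= 1, degree %in% 0:2,
            fallback %in% c("auto", "force", "off"),
            scale_mode %in% c("common", "per_block"),
            order_alpha > 0, order_alpha <= 1,
            blank_ratio > 0,
            is.finite(cv_max), cv_max >= 0,
            outlier_p > 0, outlier_p < 1,
            ppm_tol > 0, rt_tol_min >= 0,
            alpha > 0, alpha <= 1,
            n_comp >= 1, n_folds >= 2, n_perm >= 100,
            length(seed) == 1, is.finite(seed))
  structure(list(sim = sim, tables = tables, span = span, degree = degree,
                 fallback = fallback, scale_mode = scale_mode,
                 order_alpha = order_alpha, blank_ratio = blank_ratio,
                 cv_max = cv_max, outlier_p = outlier_p, ppm_tol = ppm_tol,
                 rt_tol_min = rt_tol_min, library = library, alpha = alpha,
                 n_comp = n_comp, n_folds = n_folds, n_perm = n_perm,
                 run_multivariate = run_multivariate,
                 allow_list = allow_list, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Fixed stage order per experiment x ion-mode block: QC-loess drift
#' correction, block scaling (across blocks, from the raw medians),
#' injection-order filter, blank filter (on raw intensities), QC CV
#' filter, outlier-observation removal, annotation, per-condition
#' univariate screen with onset times, and (optionally) PCA / PLS / Q2 /
#' permutation / VIP. Correlation records from all blocks are then
#' combined into robust selection and bacterial-vs-chemical stability
#' calls.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory; when given, every stage report is
#'   written as TSV together with a `manifest.tsv` echoing all
#'   parameters, seeds and versions.
#' @return List with `tables` (final per-block tables), `reports`
#'   (per-block stage reports), `annotations`, `records` (combined
#'   correlation records), `onsets`, `mva` (per-block multivariate
#'   results, or `NULL`), `calls`, `summary`, `truth` (when simulated)
#'   and `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$sim)) {
    sim <- simulate_study(cfg$sim)
    raw <- sim$tables
    truth <- sim$truth
  } else {
    raw <- cfg$tables
    truth <- NULL
  }

  corrected <- list()
  reports <- list()
  for (key in names(raw)) {
    dc <- loess_drift_correct(raw[[key]], span = cfg$span,
                              degree = cfg$degree, fallback = cfg$fallback)
    corrected[[key]] <- dc$table
    reports[[key]] <- list(drift = dc$report)
  }
  bs <- block_scale(corrected, raw = raw, mode = cfg$scale_mode)
  scaled <- bs$blocks

  annotations <- list()
  records <- list()
  onsets <- list()
  mva <- if (cfg$run_multivariate) list() else NULL
  final <- list()
  for (key in names(scaled)) {
    iof <- injection_order_filter(scaled[[key]], alpha = cfg$order_alpha)
    reports[[key]]$order_filter <- iof$report
    keep_ids <- iof$table$features$feature_id
    bf <- blank_filter(iof$table, ratio_min = cfg$blank_ratio,
                       raw = ft_subset(raw[[key]], features = keep_ids))
    reports[[key]]$blank_filter <- bf$report
    cf <- cv_filter(bf$table, cv_max = cfg$cv_max)
    reports[[key]]$cv_filter <- cf$report
    ol <- detect_outlier_observations(cf$table, p_threshold = cfg$outlier_p)
    reports[[key]]$outliers <- ol$report
    tab <- ol$table
    final[[key]] <- tab

    annotations[[key]] <- annotate(tab, cfg$library, ppm_tol = cfg$ppm_tol,
                                   rt_tol_min = cfg$rt_tol_min)
    recs <- screen_conditions(tab, alpha = cfg$alpha)
    records[[key]] <- recs
    onsets[[key]] <- onset_table(tab, recs)

    if (cfg$run_multivariate) {
      pm <- preprocess(tab)
      y <- pm$obs_meta$time_h
      pc <- pca(pm, n_comp = min(cfg$n_comp, min(dim(pm$x)) - 1))
      fit <- pls(pm, y, n_comp = cfg$n_comp)
      perm <- permutation_test(pm, y, n_comp = cfg$n_comp,
                               n_perm = cfg$n_perm, n_folds = cfg$n_folds,
                               seed = cfg$seed)
      v <- vip(fit)
      rt_recs <- recs[recs$condition == "RT", , drop = FALSE]
      conc <- NA_real_
      k <- sum(rt_recs$significant, na.rm = TRUE)
      if (k >= 1) {
        idx <- match(rt_recs$feature_id, pm$var_id)
        okm <- !is.na(idx)
        conc <- vip_pvalue_concordance(v[idx[okm]], rt_recs$p[okm],
                                       k = min(k, sum(okm)))
      }
      mva[[key]] <- list(pca = pc, pls = fit,
                         q2 = perm$q2_obs, perm_p = perm$p, vip = v,
                         vip_p_concordance = conc)
    }
  }

  all_records <- do.call(rbind, records)
  all_onsets <- do.call(rbind, onsets)
  rownames(all_records) <- rownames(all_onsets) <- NULL
  calls <- classify_calls(all_records, all_onsets,
                          allow_list = cfg$allow_list)
  summary <- summarize_calls(calls, all_records)

  manifest <- data.frame(
    key = c("package_version", "r_version", "seed", "span", "degree",
            "fallback", "scale_mode", "order_alpha", "blank_ratio",
            "cv_max", "outlier_p", "ppm_tol", "rt_tol_min", "alpha",
            "n_comp", "n_folds", "n_perm", "blocks"),
    value = c(as.character(utils::packageVersion("urostab")),
              paste(R.version$major, R.version$minor, sep = "."),
              cfg$seed, cfg$span, cfg$degree, cfg$fallback, cfg$scale_mode,
              cfg$order_alpha, cfg$blank_ratio, cfg$cv_max, cfg$outlier_p,
              cfg$ppm_tol, cfg$rt_tol_min, cfg$alpha, cfg$n_comp,
              cfg$n_folds, cfg$n_perm, paste(names(raw), collapse = ";")),
    stringsAsFactors = FALSE)

  result <- list(tables = final, reports = reports,
                 annotations = annotations, records = all_records,
                 onsets = all_onsets, mva = mva, calls = calls,
                 summary = summary, truth = truth, manifest = manifest,
                 block_factors = bs$factors)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(all_records, file.path(out_dir, "correlation_records.tsv"))
    write_results(all_onsets, file.path(out_dir, "onset_times.tsv"))
    write_results(calls, file.path(out_dir, "stability_calls.tsv"))
    write_results(summary$class_counts, file.path(out_dir, "class_counts.tsv"))
    if (!is.null(summary$experiment_counts)) {
      write_results(summary$experiment_counts,
                    file.path(out_dir, "experiment_counts.tsv"))
    }
    ann <- do.call(rbind, annotations)
    if (!is.null(ann)) {
      write_results(ann, file.path(out_dir, "annotations.tsv"))
    }
    for (key in names(reports)) {
      write_results(reports[[key]]$drift$per_feature,
                    file.path(out_dir, paste0(key, "_drift_report.tsv")))
    }
    write_results(manifest, file.path(out_dir, "manifest.tsv"))
  }
  result
}
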