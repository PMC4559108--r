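#' Coefficient of variation
#'
#' Sample (n - 1) standard deviation divided by the absolute mean. The
#' sample-SD convention is fixed because QC counts are small.
#'
#' @param values numeric vector with at least 2 finite values and
#'   non-zero mean.
#' @return Non-negative real.
#' @export
cv <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2) stop("cv needs >= 2 finite values")
  mu <- mean(v)
  if (mu == 0) stop("cv undefined: zero mean")
  stats::sd(v) / abs(mu)
}

# row-wise cv that returns NA instead of erroring (for reports)
row_cv <- function(m) {
  apply(m, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) NA_real_ else stats::sd(v) / abs(mean(v))
  })
}

#' Blank filter: remove background features
#'
#' A feature is removed iff its mean intensity in the QC injections is
#' less than `ratio_min` times its mean intensity in the blank injections
#' (strict inequality; a feature exactly at the boundary is retained).
#' Blank comparison is meaningful on raw (pre-normalisation) intensities:
#' pass the raw table via `raw` when `t` is already drift-corrected.
#'
#' @param t a [feature_table()] (the one to subset).
#' @param ratio_min required QC-to-blank mean ratio (default 2).
#' @param raw [feature_table()] whose intensities define the means;
#'   defaults to `t`.
#' @return List with `table` (surviving features) and `report`
#'   (per-feature means, ratio, pass flag). With no blank injections the
#'   filter is skipped with a warning.
#' @export
blank_filter <- function(t, ratio_min = 2, raw = t) {
  stopifnot(inherits(t, "feature_table"), inherits(raw, "feature_table"),
            ratio_min > 0)
  if (!identical(raw$features$feature_id, t$features$feature_id)) {
    stop("`raw` must carry the same features as `t`")
  }
  if (!any(is_blank(raw))) {
    warning("no blank injections: blank filter skipped")
    return(list(table = t, report = NULL))
  }
  if (!any(is_qc(raw))) stop("blank filter needs >= 1 QC injection")
  mean_qc <- rowMeans(raw$intensities[, is_qc(raw), drop = FALSE],
                      na.rm = TRUE)
  mean_blank <- rowMeans(raw$intensities[, is_blank(raw), drop = FALSE],
                         na.rm = TRUE)
  fail <- mean_qc < ratio_min * mean_blank
  report <- data.frame(feature_id = t$features$feature_id,
                       mean_qc = mean_qc, mean_blank = mean_blank,
                       blank_ratio = ifelse(mean_blank > 0,
                                            mean_qc / mean_blank, Inf),
                       pass = !fail, stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(table = ft_subset(t, features = !fail), report = report)
}

#' QC repeatability filter
#'
#' A feature is removed iff its CV over the QC injections exceeds
#' `cv_max` (strict inequality: a feature at exactly `cv_max` is
#' retained). Computed on the intensities of `t`, which in the standard
#' pipeline are drift-corrected.
#'
#' @param t a [feature_table()] with >= 3 QC injections.
#' @param cv_max maximal tolerated QC CV (default 0.30).
#' @return List with `table` (surviving features) and `report`
#'   (per-feature QC CV and pass flag).
#' @export
cv_filter <- function(t, cv_max = 0.30) {
  stopifnot(inherits(t, "feature_table"), cv_max >= 0)
  if (sum(is_qc(t)) < 3) stop("cv filter needs >= 3 QC injections")
  qc_cv <- row_cv(t$intensities[, is_qc(t), drop = FALSE])
  fail <- !is.na(qc_cv) & qc_cv > cv_max
  report <- data.frame(feature_id = t$features$feature_id, qc_cv = qc_cv,
                       pass = !fail, stringsAsFactors = FALSE)
  list(table = ft_subset(t, features = !fail), report = report)
}

#' Detect outlier study injections from their intensity-distribution
#' quantiles
#'
#' Screens each study injection for a globally aberrant intensity
#' distribution. For each study injection the deciles of its log10
#' intensity distribution are computed; each decile is turned into a
#' robust z-score against the same decile of the reference injections
#' (median/MAD); the injection's outlier statistic is the maximum |z|
#' over deciles, and its p-value is the two-sided Student-t tail (with
#' the reference size as degrees of freedom, acknowledging that the MAD
#' is itself estimated) with Bonferroni correction over the deciles.
#' Injections with `p < p_threshold` are removed.
#'
#' The reference set is the other study injections of the same storage
#' condition (falling back to all other study injections when the
#' condition has fewer than 7 members): deliberate condition-wide
#' effects, such as the ionisation shift induced by a boric-acid
#' preservative, move every decile of a whole arm and must not read as
#' outliers.
#'
#' This decile-z construction is an explicit stand-in for published
#' quantile-based outlier procedures; the screen targets gross
#' acquisition failures (an injection uniformly off in intensity), not
#' subtle multivariate outliers.
#'
#' @param t a [feature_table()] with >= 8 study injections.
#' @param p_threshold removal threshold (default 1e-3).
#' @return List with `removed` (injection ids), `table` (`t` without
#'   them) and `report` (per-injection statistic and p).
#' @export
detect_outlier_observations <- function(t, p_threshold = 1e-3) {
  stopifnot(inherits(t, "feature_table"), p_threshold > 0, p_threshold < 1)
  st_idx <- which(is_study(t))
  if (length(st_idx) < 8) stop("needs >= 8 study injections")
  probs <- seq(0.1, 0.9, by = 0.1)
  logm <- log10(pmax(t$intensities[, st_idx, drop = FALSE],
                     .Machine$double.xmin))
  deciles <- apply(logm, 2, stats::quantile, probs = probs, na.rm = TRUE,
                   names = FALSE)                       # 9 x n_study
  cond <- t$injections$condition[st_idx]
  zmax <- rep(NA_real_, length(st_idx))
  n_ref <- rep(NA_real_, length(st_idx))
  for (j in seq_along(st_idx)) {
    ref <- which(cond == cond[j])
    ref <- ref[ref != j]
    if (length(ref) < 6) ref <- seq_along(st_idx)[-j]
    n_ref[j] <- length(ref)
    zs <- vapply(seq_along(probs), function(d) {
      others <- deciles[d, ref]
      med <- stats::median(others)
      mad <- stats::mad(others)
      if (mad == 0) return(NA_real_) # degenerate decile: skipped
      abs(deciles[d, j] - med) / mad
    }, numeric(1))
    zmax[j] <- if (all(is.na(zs))) 0 else max(zs, na.rm = TRUE)
  }
  p <- pmin(1, 2 * stats::pt(-zmax, df = n_ref - 1) * length(probs))
  removed <- t$injections$injection_id[st_idx][p < p_threshold]
  report <- data.frame(injection_id = t$injections$injection_id[st_idx],
                       outlier_z = zmax, p = p,
                       removed = p < p_threshold, stringsAsFactors = FALSE)
  keep <- !(t$injections$injection_id %in% removed)
  list(removed = removed, table = ft_subset(t, injections = keep),
       report = report)
}
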