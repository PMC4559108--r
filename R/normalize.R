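#' QC-based loess correction of injection-order signal drift
#'
#' For each feature, a locally weighted polynomial (loess, tricube
#' weights) of the stated degree is fitted to the QC intensities as a
#' function of injection order, and every injection's intensity is
#' divided by the model prediction at its order. Predictions for orders
#' outside the QC range are clamped to the prediction at the nearest QC
#' order (unconstrained polynomial extrapolation beyond the first/last QC
#' is unstable). Features for which any needed prediction is
#' non-positive are routed to the per-feature median fallback and
#' reported as such.
#'
#' When `fallback = "auto"`, the whole block is additionally re-routed to
#' the median fallback when the QC model is judged non-representative:
#' either the median QC CV increases after correction, or more than 10
#' percent of features have non-positive predictions.
#'
#' @param t a [feature_table()] with at least `degree + 2` QC injections.
#' @param span loess span in `(0, 1]` (default 0.75, the conventional
#'   default; the value is echoed in the report for reproducibility).
#'   With few QCs the span is floored at `(degree + 3) / n_qc` so every
#'   local window keeps enough positively weighted points; the effective
#'   span actually used appears in the report.
#' @param degree local polynomial degree (default 2, local quadratic).
#' @param fallback `"auto"` (default), `"force"` (median fallback for all
#'   features) or `"off"` (non-positive predictions raise an error).
#' @return List with `table` (corrected [feature_table()]) and `report`
#'   (a `drift_report`: per-feature method and QC CV before/after, the
#'   per-feature x injection divisor matrix, span, degree, and whether
#'   the block was re-routed).
#' @export
loess_drift_correct <- function(t, span = 0.75, degree = 2,
                                fallback = c("auto", "force", "off")) {
  stopifnot(inherits(t, "feature_table"), span > 0, span <= 1,
            degree %in% 0:2)
  fallback <- match.arg(fallback)
  qc <- is_qc(t)
  n_qc <- sum(qc)
  if (n_qc < degree + 2) {
    stop("needs at least degree + 2 = ", degree + 2, " QC injections (",
         n_qc, " found); use median_fallback()")
  }
  m <- t$intensities
  orders <- t$injections$order
  qc_orders <- orders[qc]
  pred_orders <- pmin(pmax(orders, min(qc_orders)), max(qc_orders))
  # with few QCs the window must still hold degree + 3 points: the
  # tricube weight of the window's farthest point is exactly zero, so a
  # narrower window leaves the local polynomial rank-deficient
  span_eff <- max(span, min(1, (degree + 3) / n_qc))

  nf <- nrow(m)
  divisors <- matrix(NA_real_, nf, ncol(m), dimnames = dimnames(m))
  method <- rep("loess_qc", nf)
  for (f in seq_len(nf)) {
    yq <- m[f, qc]
    fit <- try(suppressWarnings(
      stats::loess(yq ~ qc_orders, span = span_eff, degree = degree,
                   control = stats::loess.control(surface = "direct"))),
      silent = TRUE)
    pred <- if (inherits(fit, "try-error")) rep(NA_real_, ncol(m)) else
      suppressWarnings(
        stats::predict(fit, newdata = data.frame(qc_orders = pred_orders)))
    if (anyNA(pred) || any(pred <= 0)) {
      method[f] <- "median_fallback"
      med <- stats::median(m[f, !is_blank(t)], na.rm = TRUE)
      pred <- rep(if (is.finite(med) && med > 0) med else NA_real_, ncol(m))
    }
    divisors[f, ] <- pred
  }
  frac_routed <- mean(method == "median_fallback")
  if (fallback == "off" && frac_routed > 0) {
    stop(sum(method == "median_fallback"),
         " feature(s) with non-positive loess predictions; ",
         "set fallback = \"auto\" or use median_fallback()")
  }
  if (fallback == "force") {
    method[] <- "median_fallback"
    med <- apply(m[, !is_blank(t), drop = FALSE], 1, stats::median,
                 na.rm = TRUE)
    med[!is.finite(med) | med <= 0] <- NA_real_
    divisors <- matrix(med, nf, ncol(m), dimnames = dimnames(m))
  }

  corrected <- m / divisors
  corrected[is.na(divisors)] <- m[is.na(divisors)] # unscalable: left as is

  cv_row <- function(mm) apply(mm, 1, function(v) {
    mu <- mean(v, na.rm = TRUE)
    if (!is.finite(mu) || mu == 0) NA_real_ else
      stats::sd(v, na.rm = TRUE) / abs(mu)
  })
  cv_before <- cv_row(m[, qc, drop = FALSE])
  cv_after <- cv_row(corrected[, qc, drop = FALSE])

  rerouted <- FALSE
  if (fallback == "auto") {
    not_representative <-
      stats::median(cv_after, na.rm = TRUE) >
        stats::median(cv_before, na.rm = TRUE) || frac_routed > 0.10
    if (not_representative) {
      rerouted <- TRUE
      fb <- median_fallback(t)
      corrected <- fb$table$intensities
      divisors <- matrix(fb$divisor, nf, ncol(m), dimnames = dimnames(m))
      method[] <- "median_fallback"
      cv_after <- cv_row(corrected[, qc, drop = FALSE])
    }
  }

  out <- feature_table(corrected, t$features, t$injections)
  report <- structure(
    list(per_feature = data.frame(feature_id = t$features$feature_id,
                                  method = method,
                                  qc_cv_before = cv_before,
                                  qc_cv_after = cv_after,
                                  stringsAsFactors = FALSE),
         divisors = divisors, span = span, span_eff = span_eff,
         degree = degree, rerouted = rerouted),
    class = "drift_report")
  list(table = out, report = report)
}

#' Per-feature median normalisation (drift-correction fallback)
#'
#' Divides each feature's intensities by that feature's median over all
#' non-blank injections. Used when the QC values are not representative
#' of the drift (no obvious drift, or a failing QC model). Features with
#' a non-positive median are flagged, left unscaled and reported with a
#' warning.
#'
#' @param t a [feature_table()].
#' @return List with `table` (normalised [feature_table()]), `divisor`
#'   (per-feature median used) and `flagged` (ids left unscaled).
#' @export
median_fallback <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  m <- t$intensities
  med <- apply(m[, !is_blank(t), drop = FALSE], 1, stats::median,
               na.rm = TRUE)
  bad <- !is.finite(med) | med <= 0
  flagged <- t$features$feature_id[bad]
  if (any(bad)) {
    warning(sum(bad), " feature(s) with non-positive median left unscaled: ",
            paste(utils::head(flagged, 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "")
  }
  div <- ifelse(bad, 1, med)
  out <- feature_table(m / div, t$features, t$injections)
  list(table = out, divisor = stats::setNames(med, t$features$feature_id),
       flagged = flagged)
}

#' Rescale drift-corrected blocks to a common intensity level
#'
#' After division by the drift model, relative intensities are close to 1.
#' To restore meaningful values, every block's corrected intensities are
#' multiplied by a common factor equal to the geometric mean over blocks
#' of the block raw-intensity medians (`mode = "common"`, the default).
#' `mode = "per_block"` instead multiplies each block by its own raw
#' median, equalising none but restoring each block's native scale. The
#' step is a pure rescaling: it changes no rank statistic within a block,
#' no CV, and no multivariate model after unit-variance scaling.
#'
#' @param blocks list of drift-corrected [feature_table()]s.
#' @param raw list of the matching raw [feature_table()]s whose intensity
#'   medians define the factor; defaults to `blocks` themselves.
#' @param mode `"common"` or `"per_block"`.
#' @return List with `blocks` (rescaled) and `factors` (per-block factor
#'   applied).
#' @export
block_scale <- function(blocks, raw = blocks,
                        mode = c("common", "per_block")) {
  mode <- match.arg(mode)
  stopifnot(length(blocks) >= 1, length(raw) == length(blocks))
  med <- vapply(raw, function(b) {
    stopifnot(inherits(b, "feature_table"))
    stats::median(b$intensities[is.finite(b$intensities)])
  }, numeric(1))
  if (any(!is.finite(med) | med <= 0)) {
    stop("non-positive raw intensity median in block(s): ",
         paste(which(!is.finite(med) | med <= 0), collapse = ", "))
  }
  factors <- if (mode == "common") {
    rep(exp(mean(log(med))), length(blocks))
  } else {
    med
  }
  out <- mapply(function(b, f) {
    feature_table(b$intensities * f, b$features, b$injections)
  }, blocks, factors, SIMPLIFY = FALSE)
  names(out) <- names(blocks)
  list(blocks = out, factors = stats::setNames(factors, names(blocks)))
}

#' Discard features still correlated with injection order
#'
#' After drift correction, a few features may remain correlated with
#' injection order; they are screened by Spearman correlation of the
#' corrected intensity against injection order over the study injections,
#' with Benjamini-Hochberg adjustment across features, and discarded at
#' `q < alpha`. A constant feature has undefined rank correlation and is
#' retained (treated as rho = 0).
#'
#' @param t a drift-corrected [feature_table()] with >= 5 study
#'   injections.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return List with `table` (surviving features), `discarded` (feature
#'   ids) and `report` (per-feature rho, p, q).
#' @export
injection_order_filter <- function(t, alpha = 0.05) {
  stopifnot(inherits(t, "feature_table"), alpha > 0, alpha <= 1)
  st <- is_study(t)
  if (sum(st) < 5) stop("needs >= 5 study injections")
  ord <- t$injections$order[st]
  res <- t(apply(t$intensities[, st, drop = FALSE], 1, function(v) {
    s <- spearman(v, ord)
    c(s$rho, s$p)
  }))
  rho <- res[, 1]
  p <- res[, 2]
  p[is.na(rho)] <- 1
  rho[is.na(rho)] <- 0
  q <- bh_fdr(p)
  drop <- q < alpha
  report <- data.frame(feature_id = t$features$feature_id, rho = rho,
                       p = p, q = q, discarded = drop,
                       stringsAsFactors = FALSE)
  list(table = ft_subset(t, features = !drop),
       discarded = t$features$feature_id[drop],
       report = report)
}
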