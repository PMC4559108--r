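#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of the average-rank-transformed vectors
#' (ties receive average ranks). The p-value uses the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom;
#' for |rho| = 1 (where the t statistic degenerates) the exact
#' permutation tail `2 / n!` is reported instead. If either vector has
#' zero rank variance, rho is undefined and `NA` is returned (reported
#' as non-significant downstream).
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return List with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("spearman needs n >= 4")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("spearman needs >= 4 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(rx, ry)
  list(rho = rho, p = spearman_p(rho, n))
}

spearman_p <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  perfect <- !is.na(rho) & abs(rho) >= 1 - 1e-12
  p[perfect] <- pmin(1, exp(log(2) - lfactorial(n)))
  reg <- !is.na(rho) & !perfect
  tstat <- rho[reg] * sqrt((n - 2) / (1 - rho[reg]^2))
  p[reg] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q(i) = min over j >= i of (m * p(j) / j)` on the sorted p-values,
#' mapped back to the input order and capped at 1.
#'
#' @param pvalues numeric vector with all values in `[0, 1]` (`NA`
#'   allowed and propagated).
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  p <- pvalues
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m == 0) return(q)
  o <- order(pp, decreasing = TRUE) # largest p first: running min is cummin
  qq <- pmin(1, cummin(m / seq.int(m, 1) * pp[o]))
  qo <- numeric(m)
  qo[o] <- qq
  q[ok] <- qo
  q
}

#' Per-condition Spearman screen of intensity versus storage duration
#'
#' For every feature, correlates intensity with storage time over the
#' study injections of one condition (all replicates pooled), then
#' adjusts across features with Benjamini-Hochberg. The BH family is the
#' set of features within one (experiment, condition, ion mode) table,
#' matching a per-condition screen.
#'
#' @param t a [feature_table()] of a single experiment x ion-mode block.
#' @param condition one of the conditions present in `t`.
#' @param alpha FDR threshold (default 0.01).
#' @return Data frame of correlation records: `feature_id`, `experiment`,
#'   `condition`, `ion_mode`, `rho`, `p`, `q`, `significant`, `sign`
#'   (`"+"`, `"-"` or `"ns"`).
#' @export
correlate_with_time <- function(t, condition, alpha = 0.01) {
  stopifnot(inherits(t, "feature_table"), alpha > 0, alpha <= 1)
  experiment <- unique(t$injections$experiment)
  mode <- unique(t$injections$ion_mode)
  if (length(experiment) != 1 || length(mode) != 1) {
    stop("table must hold a single experiment x ion-mode block")
  }
  sel <- is_study(t) & t$injections$condition %in% condition
  if (!any(sel)) stop("condition not present: ", condition)
  time_h <- t$injections$time_h[sel]
  if (length(unique(time_h)) < 4) {
    stop("needs >= 4 distinct time points for condition ", condition)
  }
  m <- t$intensities[, sel, drop = FALSE]
  n <- ncol(m)
  ranks <- t(apply(m, 1, rank))
  rt <- rank(time_h)
  sds <- apply(ranks, 1, stats::sd)
  rho <- rep(NA_real_, nrow(m))
  okv <- sds > 0 & stats::sd(rt) > 0
  if (any(okv)) {
    rho[okv] <- as.numeric(stats::cor(t(ranks[okv, , drop = FALSE]), rt))
  }
  p <- spearman_p(rho, n)
  q <- bh_fdr(p)
  significant <- !is.na(q) & q < alpha
  data.frame(feature_id = t$features$feature_id, experiment = experiment,
             condition = condition, ion_mode = mode, rho = rho, p = p,
             q = q, significant = significant,
             sign = ifelse(significant, ifelse(rho > 0, "+", "-"), "ns"),
             stringsAsFactors = FALSE)
}

#' Screen every condition of a block
#'
#' @param t a [feature_table()] block.
#' @param conditions conditions to screen (default: all present).
#' @param alpha FDR threshold.
#' @return Row-bound correlation records (see [correlate_with_time()]).
#' @export
screen_conditions <- function(t, conditions = NULL, alpha = 0.01) {
  if (is.null(conditions)) {
    conditions <- unique(stats::na.omit(t$injections$condition))
  }
  do.call(rbind, lapply(conditions, correlate_with_time, t = t,
                        alpha = alpha))
}

#' Onset time of a concentration trend
#'
#' The earliest time point at which all replicate intensities lie beyond
#' the full T0 replicate range in the trend direction: for a positive
#' trend, `min(replicates at t) > max(replicates at T0)`; for a negative
#' trend, `max(at t) < min(at T0)`. This is the strictest reading of
#' "triplicate concentrations all above (below) the T0 triplicate
#' concentrations": deterministic and conservative.
#'
#' @param time_h numeric vector of storage times (replicates repeated),
#'   containing time 0.
#' @param intensity matching intensities.
#' @param sign `"+"` or `"-"`.
#' @return List with `onset_h` (an observed time point, or `NA` if the
#'   criterion is never met), `direction` (`"above"`/`"below"`) and
#'   `skipped` (time points without usable replicates).
#' @export
onset_time <- function(time_h, intensity, sign = c("+", "-")) {
  sign <- match.arg(sign)
  stopifnot(length(time_h) == length(intensity))
  t0 <- intensity[time_h == 0 & is.finite(intensity)]
  if (!length(t0)) stop("no T0 replicates")
  later <- sort(unique(time_h[time_h > 0]))
  skipped <- numeric(0)
  for (tp in later) {
    vals <- intensity[time_h == tp]
    if (!length(vals) || anyNA(vals)) {
      skipped <- c(skipped, tp)
      next
    }
    hit <- if (sign == "+") min(vals) > max(t0) else max(vals) < min(t0)
    if (hit) {
      return(list(onset_h = tp,
                  direction = if (sign == "+") "above" else "below",
                  skipped = skipped))
    }
  }
  list(onset_h = NA_real_,
       direction = if (sign == "+") "above" else "below", skipped = skipped)
}

#' Onset times for a set of correlation records
#'
#' For each significant record, extracts the feature's trajectory in the
#' record's condition from the table and applies [onset_time()] with the
#' record's trend sign.
#'
#' @param t the [feature_table()] block the records came from.
#' @param records correlation records (see [correlate_with_time()]).
#' @return Data frame `feature_id`, `experiment`, `condition`,
#'   `onset_h`, `direction` (rows only for significant records).
#' @export
onset_table <- function(t, records) {
  sig <- records[records$significant, , drop = FALSE]
  if (!nrow(sig)) {
    return(data.frame(feature_id = character(0), experiment = character(0),
                      condition = character(0), onset_h = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  out <- lapply(seq_len(nrow(sig)), function(i) {
    r <- sig[i, ]
    sel <- is_study(t) & t$injections$condition %in% r$condition
    fi <- match(r$feature_id, t$features$feature_id)
    res <- onset_time(t$injections$time_h[sel], t$intensities[fi, sel],
                      r$sign)
    data.frame(feature_id = r$feature_id, experiment = r$experiment,
               condition = r$condition, onset_h = res$onset_h,
               direction = res$direction, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
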