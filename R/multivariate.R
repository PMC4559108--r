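#' Log10 / mean-centre / unit-variance preprocessing
#'
#' Builds the observations x variables matrix used by PCA and PLS from
#' the study injections of a feature table: intensities are log10
#' transformed, then each variable is mean-centred and unit-variance
#' scaled. Zeros are replaced by half the smallest positive value of the
#' feature before the log (and reported); all-zero and constant features
#' are dropped (and reported).
#'
#' @param t a [feature_table()].
#' @return An object of class `preprocessed_matrix`: `x` (matrix, study
#'   injections x retained features), `means`/`scales` (per retained
#'   feature, on the log10 scale), `obs_id`, `var_id`, `dropped`
#'   (feature ids), `zero_replaced` (feature ids with replaced zeros).
#' @export
preprocess <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  st <- is_study(t)
  if (sum(st) < 3) stop("needs >= 3 study injections")
  m <- t$intensities[, st, drop = FALSE]
  zero_replaced <- character(0)
  dropped <- character(0)
  keep <- rep(TRUE, nrow(m))
  for (f in seq_len(nrow(m))) {
    v <- m[f, ]
    if (any(v == 0, na.rm = TRUE)) {
      pos <- v[v > 0 & is.finite(v)]
      if (!length(pos)) {
        keep[f] <- FALSE
        dropped <- c(dropped, t$features$feature_id[f])
        next
      }
      m[f, v == 0] <- min(pos) / 2
      zero_replaced <- c(zero_replaced, t$features$feature_id[f])
    }
  }
  x <- t(log10(m[keep, , drop = FALSE]))
  sds <- apply(x, 2, stats::sd)
  const <- !is.finite(sds) | sds == 0
  if (any(const)) {
    dropped <- c(dropped, colnames(x)[const])
    x <- x[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  means <- colMeans(x)
  x <- scale(x, center = means, scale = sds)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  structure(list(x = x, means = means, scales = sds,
                 obs_id = t$injections$injection_id[st],
                 obs_meta = t$injections[st, , drop = FALSE],
                 var_id = colnames(x), dropped = dropped,
                 zero_replaced = zero_replaced),
            class = "preprocessed_matrix")
}

as_obs_matrix <- function(m) {
  if (inherits(m, "preprocessed_matrix")) m$x else as.matrix(m)
}

#' Principal component analysis by singular-value decomposition
#'
#' Components are the right singular vectors of the (already centred)
#' matrix; the explained-variance fraction of component `a` is its
#' squared singular value over the total. The sign of each component is
#' fixed so that the largest-magnitude element of its loading vector is
#' positive, making outputs reproducible across platforms.
#'
#' @param m a `preprocessed_matrix` (or a plain centred matrix,
#'   observations x variables).
#' @param n_comp number of components (<= matrix rank).
#' @return List with `scores` (obs x n_comp), `loadings`
#'   (vars x n_comp), `explained` (fractions, one per component).
#' @export
pca <- function(m, n_comp = 2) {
  x <- as_obs_matrix(m)
  sv <- svd(x)
  tol <- max(dim(x)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (n_comp > rank) {
    stop("n_comp (", n_comp, ") exceeds matrix rank (", rank, ")")
  }
  flip <- vapply(seq_len(n_comp), function(a) {
    v <- sv$v[, a]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(n_comp), drop = FALSE] %*%
                    diag(sv$d[seq_len(n_comp)], n_comp), 2, flip, `*`)
  loadings <- sweep(sv$v[, seq_len(n_comp), drop = FALSE], 2, flip, `*`)
  rownames(loadings) <- colnames(x)
  list(scores = scores, loadings = loadings,
       explained = sv$d[seq_len(n_comp)]^2 / sum(sv$d^2))
}

#' PLS1 regression by NIPALS with deflation
#'
#' Fits a partial least-squares regression of a single response (the
#' storage duration) on the preprocessed intensity matrix. Components
#' are extracted by NIPALS: the weight vector is the (normalised)
#' covariance of the residual X with the residual y, scores are the
#' projection of X on the weights, and X and y are deflated by the
#' rank-one approximations before the next component. `x` is centred
#' with the training means internally (a no-op for an already-centred
#' preprocessed matrix); `y` is centred internally.
#'
#' @param m a `preprocessed_matrix` or numeric matrix (obs x vars).
#' @param y numeric response, one value per observation, non-constant.
#' @param n_comp number of components (default 2).
#' @return An object of class `pls_model`: `scores` (T), `weights` (W,
#'   orthonormal columns), `loadings` (P), `y_loadings` (c), `coef`
#'   (regression vector on the centred scale), `x_center`, `y_center`,
#'   `expl_y` (cumulative fraction of Y variance explained per
#'   component), `ssy` (Y sum of squares explained per component),
#'   `n_comp`.
#' @export
pls <- function(m, y, n_comp = 2) {
  x <- as_obs_matrix(m)
  y <- as.numeric(y)
  if (length(y) != nrow(x)) stop("y length must equal observations")
  if (stats::sd(y) == 0) stop("constant response")
  if (n_comp < 1 || n_comp > min(dim(x))) stop("invalid n_comp")
  x_center <- colMeans(x)
  xr <- sweep(x, 2, x_center)
  y_center <- mean(y)
  u <- y - y_center
  ssy_tot <- sum(u^2)
  n_var <- ncol(x)
  W <- matrix(0, n_var, n_comp)
  P <- matrix(0, n_var, n_comp)
  Tm <- matrix(0, nrow(x), n_comp)
  cvec <- numeric(n_comp)
  ssy <- numeric(n_comp)
  for (a in seq_len(n_comp)) {
    w <- crossprod(xr, u)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) {
      # X residual carries no covariance with y: trailing components are
      # null and kept as zeros
      break
    }
    w <- w / nw
    tt <- xr %*% w
    tt2 <- sum(tt^2)
    p <- crossprod(xr, tt) / tt2
    cc <- sum(u * tt) / tt2
    xr <- xr - tcrossprod(tt, p)
    u <- u - cc * tt
    W[, a] <- w
    P[, a] <- p
    Tm[, a] <- tt
    cvec[a] <- cc
    ssy[a] <- cc^2 * tt2
  }
  # regression vector B = W (P'W)^-1 c on the centred scale
  pw <- crossprod(P, W)
  coef <- tryCatch(W %*% solve(pw, cvec),
                   error = function(e) W %*% MASS_ginv(pw) %*% cvec)
  rownames(W) <- rownames(P) <- colnames(x)
  structure(list(scores = Tm, weights = W, loadings = P,
                 y_loadings = cvec, coef = as.numeric(coef),
                 x_center = x_center, y_center = y_center,
                 expl_y = cumsum(ssy) / ssy_tot, ssy = ssy,
                 n_comp = n_comp),
            class = "pls_model")
}

# minimal Moore-Penrose pseudoinverse (degenerate P'W only)
MASS_ginv <- function(a, tol = sqrt(.Machine$double.eps)) {
  sv <- svd(a)
  pos <- sv$d > tol * sv$d[1]
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  x <- as_obs_matrix(newdata)
  as.numeric(sweep(x, 2, object$x_center) %*% object$coef) + object$y_center
}

# venetian-blind fold assignment: every n_folds-th observation by sorted y
venetian_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  folds[order(y)] <- rep_len(seq_len(n_folds), length(y))
  folds
}

#' Cross-validated Q2 of a PLS model
#'
#' Venetian-blind cross-validation: observations are sorted by the
#' response and dealt into `n_folds` interleaved folds, a deterministic
#' scheme standard in metabolomics software. For each fold, a PLS model
#' is fitted on the remaining observations and used to predict the
#' held-out ones; `Q2 = 1 - PRESS / TSS` with TSS on the centred
#' response.
#'
#' @param m a `preprocessed_matrix` or numeric matrix.
#' @param y numeric response.
#' @param n_comp PLS components (default 2).
#' @param n_folds folds, between 2 and the number of observations
#'   (default 7; `n_folds = n` is leave-one-out).
#' @return Q2 value (<= 1; can be negative for models worse than the
#'   mean).
#' @export
q2 <- function(m, y, n_comp = 2, n_folds = 7) {
  x <- as_obs_matrix(m)
  y <- as.numeric(y)
  n <- nrow(x)
  if (n_folds < 2 || n_folds > n) stop("n_folds must be in [2, n]")
  folds <- venetian_folds(y, n_folds)
  press <- 0
  for (k in seq_len(n_folds)) {
    test <- folds == k
    if (!any(test) || all(test)) stop("empty training or test fold")
    fit <- pls(x[!test, , drop = FALSE], y[!test], n_comp)
    pred <- predict(fit, x[test, , drop = FALSE])
    press <- press + sum((y[test] - pred)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Permutation test of Q2
#'
#' The observed Q2 is compared with the distribution of Q2 values of
#' models fitted after random permutation of the response labels;
#' `p = (1 + #\{permuted Q2 >= observed\}) / (n_perm + 1)` (the +1
#' smoothing makes p = 0 unattainable).
#'
#' @param m a `preprocessed_matrix` or numeric matrix.
#' @param y numeric response.
#' @param n_comp PLS components.
#' @param n_perm number of permutations (>= 99; default 1000, the study
#'   convention).
#' @param n_folds cross-validation folds.
#' @param seed integer seed for the permutations.
#' @return List with `p`, `q2_obs` and `q2_perm` (the null
#'   distribution).
#' @export
permutation_test <- function(m, y, n_comp = 2, n_perm = 1000, n_folds = 7,
                             seed = 1) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  x <- as_obs_matrix(m)
  q2_obs <- q2(x, y, n_comp, n_folds)
  set.seed(seed)
  q2_perm <- vapply(seq_len(n_perm), function(i) {
    q2(x, sample(y), n_comp, n_folds)
  }, numeric(1))
  list(p = (1 + sum(q2_perm >= q2_obs)) / (n_perm + 1),
       q2_obs = q2_obs, q2_perm = q2_perm)
}

#' Variable importance in projection (VIP)
#'
#' Standard VIP scores:
#' `VIP_j = sqrt(p * sum_a(SSY_a * (w_ja / ||w_a||)^2) / sum_a(SSY_a))`
#' with `p` the number of variables and `SSY_a` the Y sum of squares
#' explained by component `a`. The mean of the squared VIPs equals 1 by
#' construction.
#'
#' @param model a fitted [pls()] model.
#' @return Named vector of non-negative VIP scores, one per variable.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ssy <- model$ssy
  if (sum(ssy) <= 0) stop("model explains no Y variance")
  W <- model$weights
  wnorm2 <- colSums(W^2)
  wnorm2[wnorm2 == 0] <- 1 # null trailing components contribute nothing
  p <- nrow(W)
  scores <- sqrt(p * as.numeric((W^2 %*% (ssy / wnorm2))) / sum(ssy))
  stats::setNames(scores, rownames(W))
}

#' Concordance between top VIP and top p-value rankings
#'
#' Fraction of variables shared between the `k` highest VIP scores and
#' the `k` smallest p-values. Ties at rank `k` are broken by position
#' (id order) and reported via a message.
#'
#' @param vips,pvalues aligned numeric vectors.
#' @param k set size (<= length).
#' @return Fraction in `[0, 1]`.
#' @export
vip_pvalue_concordance <- function(vips, pvalues, k) {
  stopifnot(length(vips) == length(pvalues), k >= 1, k <= length(vips))
  ov <- order(-vips, seq_along(vips))
  op <- order(pvalues, seq_along(pvalues))
  tie_v <- k < length(vips) && vips[ov[k]] == vips[ov[k + 1]]
  tie_p <- k < length(pvalues) && pvalues[op[k]] == pvalues[op[k + 1]]
  if (tie_v || tie_p) {
    message("ties at rank ", k, " broken by id order")
  }
  length(intersect(ov[seq_len(k)], op[seq_len(k)])) / k
}
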