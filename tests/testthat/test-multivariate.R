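test_that("preprocessing gives centred unit-variance log10 columns", {
  vals <- rbind(c(10, 100, 1000), c(7, 7, 7), c(0, 50, 100))
  ft <- make_ft(vals, rep("study", 3), condition = "RT",
                time_h = c(0, 12, 24), replicate = 1)
  pm <- preprocess(ft)
  expect_equal(unname(pm$x[, "F001"]), c(-1, 0, 1))
  expect_identical(pm$dropped, "F002") # constant column dropped
  expect_identical(pm$zero_replaced, "F003")
  expect_equal(unname(pm$x[1, "F003"]),
               (log10(25) - mean(log10(c(25, 50, 100)))) /
                 stats::sd(log10(c(25, 50, 100))))
  # stored means/scales invert back to the log10 data
  back <- sweep(sweep(pm$x, 2, pm$scales, `*`), 2, pm$means, `+`)
  expect_equal(unname(back[, "F001"]), log10(c(10, 100, 1000)))
  cfg <- quick_cfg()
  pm2 <- preprocess(simulate_study(cfg)$tables[[1]])
  expect_equal(unname(colMeans(pm2$x)), rep(0, ncol(pm2$x)),
               tolerance = 1e-10)
  expect_equal(unname(apply(pm2$x, 2, stats::sd)), rep(1, ncol(pm2$x)),
               tolerance = 1e-10)
})

test_that("PCA matches the SVD oracle and obeys its conventions", {
  x <- matrix(stats::rnorm(60), 10, 6)
  x <- scale(x, scale = FALSE)
  set.seed(21)
  res <- pca(x, n_comp = 4)
  ref <- stats::prcomp(x, center = FALSE)
  for (a in 1:4) {
    expect_equal(abs(res$scores[, a]), abs(unname(ref$x[, a])),
                 tolerance = 1e-10)
    expect_equal(abs(res$loadings[, a]), abs(unname(ref$rotation[, a])),
                 tolerance = 1e-10)
    l <- res$loadings[, a]
    expect_gt(l[which.max(abs(l))], 0) # sign convention
  }
  expect_equal(res$explained,
               unname(ref$sdev[1:4]^2 / sum(ref$sdev^2)), tolerance = 1e-10)
  expect_true(all(diff(res$explained) <= 1e-12))
  expect_lte(sum(res$explained), 1 + 1e-12)

  rank1 <- outer(stats::rnorm(8), stats::rnorm(5))
  expect_equal(pca(scale(rank1, scale = FALSE), 1)$explained, 1,
               tolerance = 1e-8)
  expect_error(pca(rank1, n_comp = 5), "rank")
})

test_that("NIPALS PLS1 reproduces reference predictions and limit cases", {
  skip_if_not_installed("mixOmics")
  set.seed(22)
  x <- matrix(stats::rnorm(15 * 6), 15, 6)
  colnames(x) <- paste0("v", 1:6)
  y <- stats::rnorm(15)
  fit <- pls(x, y, n_comp = 2)
  ref <- mixOmics::pls(x, y, ncomp = 2, scale = FALSE, mode = "regression")
  pred_ref <- predict(ref, newdata = x)$predict[, 1, 2]
  expect_equal(predict(fit, x), unname(pred_ref), tolerance = 1e-8)

  # y exactly linear in one variable of an orthogonal design: a single
  # component explains everything (with correlated random columns the
  # first weight vector mixes in spurious sample correlations)
  xo <- qr.Q(qr(cbind(1, matrix(stats::rnorm(15 * 6), 15, 6))))[, -1]
  y1 <- 3 * xo[, 2]
  fit1 <- pls(xo, y1, n_comp = 1)
  expect_equal(fit1$expl_y[1], 1, tolerance = 1e-10)
  expect_equal(predict(fit1, xo), y1, tolerance = 1e-8)

  # duplicated variable gets identical weights
  xd <- cbind(x, x[, 1])
  fitd <- pls(xd, y, n_comp = 2)
  expect_equal(fitd$weights[1, ], fitd$weights[7, ], tolerance = 1e-10)

  # with n_comp = rank, PLS predictions equal OLS predictions
  xs <- matrix(stats::rnorm(20 * 4), 20, 4)
  fit_full <- pls(xs, y <- stats::rnorm(20), n_comp = 4)
  ols <- stats::lm.fit(cbind(1, xs), y)
  expect_equal(predict(fit_full, xs), unname(cbind(1, xs) %*% ols$coefficients)[, 1],
               tolerance = 1e-8)
  expect_error(pls(xs, rep(1, 20)), "constant")
  expect_true(all(diff(fit_full$expl_y) >= -1e-12))
})

test_that("Q2 separates signal from noise and handles fold boundaries", {
  set.seed(23)
  n <- 60
  x <- matrix(stats::rnorm(n * 8), n, 8)
  y <- 2 * x[, 1] - x[, 2] + stats::rnorm(n, sd = 0.05)
  expect_gt(q2(x, y, n_comp = 2, n_folds = 7), 0.9)
  q2_null <- replicate(30, q2(x, sample(y), n_comp = 2, n_folds = 7))
  expect_lt(mean(q2_null), 0.05)
  loo <- q2(x, y, n_comp = 2, n_folds = n)
  expect_true(is.finite(loo))
  expect_error(q2(x, y, n_folds = 1), "n_folds")
})

test_that("Q2 is invariant to block rescaling and response rescaling", {
  cfg <- quick_cfg()
  tab <- simulate_study(cfg)$tables[[1]]
  scl <- block_scale(list(tab))$blocks[[1]]
  pm <- preprocess(tab)
  pm_s <- preprocess(scl)
  y <- pm$obs_meta$time_h
  expect_equal(q2(pm, y), q2(pm_s, y), tolerance = 1e-10)
  expect_equal(q2(pm, y), q2(pm, y * 3.6 + 2), tolerance = 1e-10)
})

test_that("permutation p-values behave at the extremes", {
  set.seed(24)
  n <- 30
  x <- matrix(stats::rnorm(n * 8), n, 8)
  y <- x[, 1] + stats::rnorm(n, sd = 0.05)
  res <- permutation_test(x, y, n_perm = 199, seed = 31)
  expect_equal(res$p, 1 / 200) # smallest achievable with +1 smoothing
  worst <- permutation_test(x, stats::rnorm(n), n_perm = 199, seed = 31)
  expect_gt(worst$p, 0.05)
  expect_error(permutation_test(x, y, n_perm = 10), "99")
})

test_that("VIP scores satisfy the algebraic identity and rank signal first", {
  set.seed(25)
  n <- 40
  x <- matrix(stats::rnorm(n * 12), n, 12)
  y <- 1.5 * x[, 5] + stats::rnorm(n, sd = 0.2)
  fit <- pls(x, y, n_comp = 2)
  v <- vip(fit)
  expect_equal(mean(v^2), 1, tolerance = 1e-10)
  expect_equal(unname(which.max(v)), 5)
  xd <- cbind(x[, 5], x, x[, 5])
  vd <- vip(pls(xd, y, n_comp = 2))
  expect_equal(unname(vd[1]), unname(vd[14]), tolerance = 1e-10)
})

test_that("VIP/p-value concordance counts overlapping top sets", {
  v <- c(5, 4, 3, 2, 1)
  p_same <- c(0.001, 0.01, 0.1, 0.5, 0.9)
  expect_equal(vip_pvalue_concordance(v, p_same, 3), 1)
  expect_equal(vip_pvalue_concordance(v, rev(p_same), 2), 0)
  expect_message(vip_pvalue_concordance(c(3, 2, 2, 1), p_same[1:4], 2),
                 "ties")
})
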