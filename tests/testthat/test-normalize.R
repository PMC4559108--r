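test_that("constant QC intensities give a constant divisor and unit QCs", {
  set.seed(1)
  n_inj <- 24
  types <- rep("study", n_inj)
  types[c(1, 8, 16, 24)] <- "qc"
  m <- matrix(stats::runif(2 * n_inj, 50, 150), 2, n_inj)
  m[, types == "qc"] <- 40 # every QC equals c = 40
  ft <- make_ft(m, types, condition = "RT",
                time_h = rep(seq(0, 72, length.out = 20), length.out = n_inj),
                replicate = 1)
  res <- loess_drift_correct(ft, fallback = "off")
  expect_equal(unname(res$report$divisors), matrix(40, 2, n_inj),
               tolerance = 1e-10)
  expect_equal(unname(res$table$intensities[, types == "qc"]),
               matrix(1, 2, 4), tolerance = 1e-10)
  expect_equal(unname(res$table$intensities), unname(m) / 40,
               tolerance = 1e-10)
})

test_that("exactly quadratic noiseless drift is removed to numerical precision", {
  cfg <- quick_cfg(noise_cv = 0, drift_amplitude = 0.3)
  sim <- simulate_study(cfg)
  for (key in names(sim$tables)) {
    tab <- sim$tables[[key]]
    res <- loess_drift_correct(tab, span = 0.75, degree = 2,
                               fallback = "off")
    st <- is_study(res$table)
    got <- res$table$intensities[, st]
    truth <- sim$truth$blocks[[key]]
    base <- sim$truth$features$baseline[
      sim$truth$features$ion_mode == "positive"]
    want <- truth$expected / base # corrected values are QC-relative
    expect_lt(max(abs(got / want - 1)), 1e-6)
    # corrected QCs average ~1 per feature before block scaling
    qc_means <- rowMeans(res$table$intensities[, is_qc(res$table)])
    expect_equal(unname(qc_means), rep(1, nrow(got)), tolerance = 1e-8)
  }
})

test_that("features with non-positive predictions are routed to the median fallback", {
  set.seed(2)
  n_inj <- 20
  types <- rep("study", n_inj)
  types[c(1, 7, 14, 20)] <- "qc"
  m <- matrix(stats::runif(2 * n_inj, 80, 120), 2, n_inj)
  m[2, types == "qc"] <- c(100, 1e-9, 1e-9, 1e-9) # collapses through zero
  ft <- make_ft(m, types, condition = "RT",
                time_h = rep(c(0, 24, 48, 72), length.out = n_inj),
                replicate = 1)
  res <- loess_drift_correct(ft, fallback = "auto")
  expect_identical(res$report$per_feature$method[2], "median_fallback")
  expect_error(loess_drift_correct(ft, fallback = "off"), "non-positive")
})

test_that("median fallback divides by the per-feature median and flags zeros", {
  m <- rbind(rep(10, 5), c(1, 2, 3, 2, 1), rep(0, 5))
  ft <- make_ft(m, rep("study", 5), condition = "RT",
                time_h = c(0, 12, 24, 48, 72), replicate = 1)
  expect_warning(res <- median_fallback(ft), "non-positive median")
  expect_equal(unname(res$table$intensities[1, ]), rep(1, 5))
  expect_equal(unname(res$table$intensities[2, ]), c(0.5, 1, 1.5, 1, 0.5))
  expect_equal(unname(res$table$intensities[3, ]), rep(0, 5)) # unchanged
  expect_identical(res$flagged, "F003")
})

test_that("block scaling multiplies by the geometric mean of raw medians", {
  ft1 <- make_ft(matrix(10, 2, 5), rep("study", 5), condition = "RT",
                 time_h = 0, replicate = 1)
  ft2 <- make_ft(matrix(1000, 2, 5), rep("study", 5), condition = "RT",
                 time_h = 0, replicate = 1)
  corr <- list(a = make_ft(matrix(1, 2, 5), rep("study", 5),
                           condition = "RT", time_h = 0, replicate = 1),
               b = make_ft(matrix(2, 2, 5), rep("study", 5),
                           condition = "RT", time_h = 0, replicate = 1))
  res <- block_scale(corr, raw = list(ft1, ft2))
  expect_equal(unname(res$factors), c(100, 100))
  expect_equal(unname(res$blocks$a$intensities[1, 1]), 100)
  expect_equal(unname(res$blocks$b$intensities[1, 1]), 200)

  one <- block_scale(corr["a"], raw = list(ft1))
  expect_equal(unname(one$factors), 10)

  per <- block_scale(corr, raw = list(ft1, ft2), mode = "per_block")
  expect_equal(unname(per$factors), c(10, 1000))
})

test_that("block scaling changes no rank statistic", {
  cfg <- quick_cfg()
  sim <- simulate_study(cfg)
  tabs <- sim$tables
  res <- block_scale(tabs)
  tab <- tabs[[1]]; scl <- res$blocks[[1]]
  sel <- is_study(tab) & tab$injections$condition == "RT"
  for (f in c(1, 10, 25)) {
    a <- spearman(tab$intensities[f, sel], tab$injections$time_h[sel])
    b <- spearman(scl$intensities[f, sel], scl$injections$time_h[sel])
    expect_equal(a$rho, b$rho)
    expect_equal(a$p, b$p)
  }
})

test_that("the injection-order filter removes order-correlated features only", {
  set.seed(4)
  n <- 20
  m <- rbind(seq_len(n) * 1.0,                    # strictly increasing
             rep(5, n),                           # constant: retained
             stats::runif(n, 90, 110))
  ft <- make_ft(m, rep("study", n), condition = "RT",
                time_h = rep(c(0, 12, 24, 48, 72), each = 4), replicate = 1)
  res <- injection_order_filter(ft, alpha = 0.05)
  expect_identical(res$discarded, "F001")
  expect_true(all(c("F002", "F003") %in% res$table$features$feature_id))

  # null Monte Carlo: discarded fraction stays near the nominal level
  set.seed(5)
  null_m <- matrix(stats::rlnorm(1000 * 30), 1000, 30)
  null_ft <- make_ft(null_m, rep("study", 30), condition = "RT",
                     time_h = rep(c(0, 12, 24, 36, 48, 72), each = 5),
                     replicate = 1)
  null_res <- injection_order_filter(null_ft, alpha = 0.05)
  # BH under the full null rejects anything at all in <= ~5 % of datasets;
  # per-feature the expected discarded fraction is far below alpha
  expect_lte(length(null_res$discarded), 0.05 * 1000)
})

test_that("loess correction reduces the median QC CV on drifting noisy data", {
  cfg <- quick_cfg(n_features = 80, drift_amplitude = 0.3, noise_cv = 0.15,
                   seed = 77)
  sim <- simulate_study(cfg)
  for (key in names(sim$tables)) {
    res <- loess_drift_correct(sim$tables[[key]])
    rep_ <- res$report$per_feature
    expect_lt(median(rep_$qc_cv_after, na.rm = TRUE),
              median(rep_$qc_cv_before, na.rm = TRUE))
  }
})
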