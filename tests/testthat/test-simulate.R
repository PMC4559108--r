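test_that("logistic growth curve has the expected asymptotes and midpoint", {
  g <- growth_params(od_baseline = 0.05, od_max = 1.0, lag_h = 24,
                     rate_per_h = 0.5)
  expect_equal(logistic_od(0, g), 0.05 + 0.95 / (1 + exp(12)))
  expect_equal(logistic_od(0, g), 0.05, tolerance = 1e-3)
  expect_equal(logistic_od(24, g), 0.05 + 0.95 / 2)
  expect_equal(logistic_od(1e6, g), 1.0)
  tt <- seq(0, 96, by = 0.5)
  expect_true(all(diff(logistic_od(tt, g)) >= 0))
  expect_error(logistic_od(NaN, g), "finite")
})

test_that("turbidity simulation is reproducible, noiseless when asked, and shaped by design", {
  g <- growth_params()
  times <- c(0, 4, 8, 12, 24, 48, 72)
  noiseless <- simulate_turbidity(times, g, n_rep = 3, noise_sd = 0, seed = 5)
  expect_equal(noiseless$od620, rep(logistic_od(times, g), each = 3))
  a <- simulate_turbidity(times, g, n_rep = 3, noise_sd = 0.05, seed = 9)
  b <- simulate_turbidity(times, g, n_rep = 3, noise_sd = 0.05, seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(a), 21)
  expect_true(all(a$od620 >= 0))
  expect_error(simulate_turbidity(times, g, noise_sd = -1), "noise_sd")
  expect_error(simulate_turbidity(rev(times), g), "sorted")
})

test_that("simulation config rejects infeasible designs", {
  expect_error(sim_config(n_features = 10, n_bacterial = 8, n_chemical = 5,
                          n_annotated = 0, library = NULL),
               "exceeds n_features")
  expect_error(sim_config(drift_amplitude = 1.2), "drift_amplitude")
  expect_error(sim_config(time_points_h = c(4, 8), experiments = "E1",
                          n_annotated = 0, library = NULL),
               "starting at 0")
})

test_that("generated blocks respect the design: counts, QC interleaving, determinism", {
  cfg <- quick_cfg()
  sim <- simulate_study(cfg)
  expect_named(sim$tables, c("Exp1.positive", "Exp2.positive"))
  for (e in cfg$experiments) {
    tab <- sim$tables[[paste0(e, ".positive")]]
    d <- cfg$design[[e]]
    n_expect <- length(d$conditions) * length(d$time_points_h) *
      cfg$n_replicates
    expect_equal(sum(is_study(tab)), n_expect)
    expect_equal(sum(is_qc(tab)), ceiling(n_expect / cfg$qc_interval) + 1)
    expect_equal(sum(is_blank(tab)), cfg$n_blanks)
    # first and last non-blank injections are QCs (drift anchored both ends)
    types <- tab$injections$type[tab$injections$type != "blank"]
    expect_identical(types[1], "qc")
    expect_identical(types[length(types)], "qc")
  }
  sim2 <- simulate_study(quick_cfg())
  expect_identical(sim$tables, sim2$tables)
  expect_identical(sim$truth$features, sim2$truth$features)
})

test_that("zero noise and zero drift yield constant replicate intensities", {
  cfg <- quick_cfg(noise_cv = 0, drift_amplitude = 0, n_bacterial = 0,
                   n_chemical = 0)
  tab <- simulate_study(cfg)$tables[["Exp1.positive"]]
  st <- is_study(tab)
  key <- paste(tab$injections$condition[st], tab$injections$time_h[st])
  for (k in unique(key)) {
    sub <- tab$intensities[, st][, key == k, drop = FALSE]
    expect_equal(apply(sub, 1, stats::sd), rep(0, nrow(sub)),
                 ignore_attr = TRUE)
  }
})

test_that("planted effects follow the generator equations", {
  cfg <- quick_cfg(noise_cv = 0, drift_amplitude = 0)
  sim <- simulate_study(cfg)
  tab <- sim$tables[["Exp1.positive"]]
  tr <- sim$truth$features
  st <- is_study(tab)
  inj <- tab$injections[st, ]
  m <- tab$intensities[, st]
  for (class in c("bacterial", "chemical")) {
    f <- tr$feature_id[tr$class == class][1]
    s <- tr$sign[tr$feature_id == f]
    rt72 <- m[f, inj$condition == "RT" & inj$time_h == 72]
    rt0 <- m[f, inj$condition == "RT" & inj$time_h == 0]
    expect_equal(mean(rt72) / mean(rt0), cfg$effect_fold_72h^s,
                 tolerance = 0.02)
    c4 <- m[f, inj$condition == "C4"]
    if (class == "bacterial") {
      expect_equal(stats::sd(c4) / mean(c4), 0, tolerance = 1e-12)
    } else {
      c4_72 <- m[f, inj$condition == "C4" & inj$time_h == 72]
      expect_equal(mean(c4_72) / mean(rt0),
                   cfg$effect_fold_72h^(s * cfg$cold_attenuation),
                   tolerance = 1e-8)
    }
  }
})

test_that("blanks stay near the configured contamination ceiling and QCs are tight", {
  cfg <- quick_cfg(noise_cv = 0.1, blank_level = 1e-4, drift_amplitude = 0)
  sim <- simulate_study(cfg)
  tab <- sim$tables[["Exp1.positive"]]
  base <- sim$truth$features$baseline[sim$truth$features$ion_mode == "positive"]
  blank_frac <- tab$intensities[, is_blank(tab)] / base
  expect_true(all(blank_frac < 1e-4 * 4)) # log-normal cv 0.3 tail bound
  qc <- tab$intensities[, is_qc(tab)]
  qc_cv <- apply(qc, 1, function(v) stats::sd(v) / mean(v))
  # before drift is injected, QC repeatability stays below the
  # study-sample noise level by design
  expect_lt(median(qc_cv), cfg$noise_cv)
})

test_that("planted unstable features separate cleanly at moderate noise", {
  cfg <- quick_cfg(n_features = 200, n_bacterial = 30, n_chemical = 30,
                   noise_cv = 0.1, effect_fold_72h = 2, seed = 5,
                   drift_amplitude = 0)
  sim <- simulate_study(cfg)
  tr <- sim$truth$features
  planted <- tr$feature_id[tr$class != "stable"]
  for (e in c("Exp1", "Exp2")) {
    tab <- sim$tables[[paste0(e, ".positive")]]
    sel <- is_study(tab) & tab$injections$condition == "RT"
    rhos <- vapply(planted, function(f) {
      abs(spearman(tab$intensities[f, sel], tab$injections$time_h[sel])$rho)
    }, numeric(1))
    expect_gte(mean(rhos > 0.8), 0.9)
  }
})

test_that("simulate_experiment returns the requested experiment's blocks", {
  cfg <- quick_cfg()
  one <- simulate_experiment(cfg, "Exp2")
  expect_named(one$tables, "positive")
  expect_identical(unique(one$tables$positive$injections$experiment), "Exp2")
})
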