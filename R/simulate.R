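#' Bacterial growth parameters (logistic OD620 curve)
#'
#' Parameters of the logistic turbidity curve used to emulate bacterial
#' overgrowth in urine kept at room temperature. The study this design
#' emulates reports growth curves only graphically, so the numeric
#' defaults here are invented: they are chosen to make overgrowth visible
#' from about 12 h after collection at a final optical density around 1.2.
#'
#' @param od_baseline OD620 of sterile urine (non-negative).
#' @param od_max plateau OD620 (> `od_baseline`).
#' @param lag_h time (h) at which the curve reaches its midpoint.
#' @param rate_per_h logistic growth rate (1/h).
#' @return A list of class `growth_params`.
#' @export
growth_params <- function(od_baseline = 0.05, od_max = 1.2,
                          lag_h = 12, rate_per_h = 0.3) {
  stopifnot(is.finite(od_baseline), od_baseline >= 0,
            is.finite(od_max), od_max > od_baseline,
            is.finite(lag_h), lag_h >= 0,
            is.finite(rate_per_h), rate_per_h > 0)
  structure(list(od_baseline = od_baseline, od_max = od_max,
                 lag_h = lag_h, rate_per_h = rate_per_h),
            class = "growth_params")
}

#' Logistic OD620 at a given storage time
#'
#' @param t_h storage time in hours (finite, non-negative; vectorised).
#' @param g a [growth_params()] object.
#' @return OD620 values: `od_baseline + (od_max - od_baseline) /
#'   (1 + exp(-rate_per_h * (t_h - lag_h)))`, monotone non-decreasing in
#'   `t_h`.
#' @export
logistic_od <- function(t_h, g) {
  stopifnot(inherits(g, "growth_params"))
  if (any(!is.finite(t_h))) stop("t_h must be finite")
  g$od_baseline + (g$od_max - g$od_baseline) /
    (1 + exp(-g$rate_per_h * (t_h - g$lag_h)))
}

#' Simulate triplicate turbidity measurements
#'
#' Draws `n_rep` OD620 readings per time point around the logistic growth
#' curve, with additive Gaussian measurement noise, clipped at zero.
#'
#' @param times_h sorted ascending storage times (h).
#' @param g a [growth_params()] object.
#' @param n_rep replicates per time point (default 3).
#' @param noise_sd Gaussian measurement noise SD in OD units (>= 0).
#' @param seed integer seed; the output is reproducible given the seed.
#' @return Tidy data frame with columns `time_h`, `replicate`, `od620`.
#' @export
simulate_turbidity <- function(times_h, g, n_rep = 3, noise_sd = 0.02,
                               seed = 1) {
  stopifnot(inherits(g, "growth_params"), n_rep >= 1)
  if (is.unsorted(times_h)) stop("times_h must be sorted ascending")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  mu <- rep(logistic_od(times_h, g), each = n_rep)
  od <- pmax(mu + stats::rnorm(length(mu), sd = noise_sd), 0)
  data.frame(time_h = rep(times_h, each = n_rep),
             replicate = rep(seq_len(n_rep), length(times_h)),
             od620 = od)
}

#' Load the demonstration spectral library
#'
#' A small synthetic library shipped with the package for demonstrations
#' and tests. It lists urinary metabolites known from the stability
#' literature (creatine, trimethylamine oxide, nucleoside derivatives,
#' ascorbic acid, urobilinoids, ...) with approximate monoisotopic ion
#' masses and invented retention times. It is NOT an authoritative
#' reference library: use [read_library()] on a curated in-house library
#' for real data.
#'
#' @return A `spectral_library` data frame.
#' @export
demo_library <- function() {
  read_library(system.file("extdata", "demo_library_synthetic.tsv",
                           package = "urostab", mustWork = TRUE))
}

#' Default two-experiment study design
#'
#' Per-experiment storage conditions and sampling grids emulating a
#' two-experiment urine-collection stability study: samples stored at room
#' temperature (`RT`), at 4 degrees C (`C4`), or at room temperature with
#' boric-acid preservative (`Pres`), collected every 4 or 12 h between 0
#' and 72 h in triplicate. Experiment 1 has no preservative arm and a
#' denser early grid; experiment 2 adds the preservative arm on a 12-h
#' grid and its bacterial growth is delayed (logistic midpoint near 48 h
#' rather than 16 h). Growth rates are chosen so the logistic rise is
#' resolved by the sampling grid: a culture that saturates between two
#' consecutive collections leaves rank ties over most of the time course.
#'
#' @return Named list (one element per experiment) with `conditions`,
#'   `time_points_h` and `growth` entries.
#' @export
default_design <- function() {
  list(
    Exp1 = list(conditions = c("RT", "C4"),
                time_points_h = c(0, 4, 8, 12, 24, 36, 48, 60, 72),
                growth = growth_params(lag_h = 16, rate_per_h = 0.15)),
    Exp2 = list(conditions = c("RT", "C4", "Pres"),
                time_points_h = c(0, 12, 24, 36, 48, 60, 72),
                growth = growth_params(lag_h = 48, rate_per_h = 0.12))
  )
}

#' Simulation configuration
#'
#' Assembles and validates all parameters of the synthetic LC-MS study
#' generator. Defaults emulate the two-experiment urine stability design
#' (see [default_design()]): 300 features per ionisation mode, triplicate
#' study samples, one pooled-urine QC injection before every block of
#' `qc_interval` study injections (and one closing the run), leading
#' blanks, smooth multiplicative injection-order drift, log-normal
#' intensity noise, and planted unstable metabolites whose intensities
#' ramp with storage time at room temperature (bacteria-driven features
#' follow the normalised growth curve; chemically unstable features ramp
#' linearly with time and are also expressed, attenuated, at 4 degrees C
#' and fully with preservative).
#'
#' @param n_features features per ionisation mode.
#' @param n_annotated number of features whose m/z and retention time are
#'   taken from `library` (per mode, capped at the number of library
#'   entries in that mode); these are the features the annotation stage
#'   can recover.
#' @param time_points_h,conditions,growth fallback design applied to every
#'   experiment when `design` is `NULL`.
#' @param n_replicates replicates per condition x time point.
#' @param experiments experiment labels.
#' @param ion_modes subset of `c("positive", "negative")`.
#' @param qc_interval one QC per this many study injections.
#' @param n_blanks number of leading blank injections.
#' @param n_contaminants features also present in blanks at study-like
#'   intensity (they fail the blank filter by construction).
#' @param blank_level blank intensity of non-contaminant features, as a
#'   fraction of the feature baseline.
#' @param drift_amplitude maximal fractional intensity loss over the run
#'   (in `[0, 1)`); the drift curve is multiplicative and
#'   quadratic-plus-linear in injection order.
#' @param noise_cv log-normal intensity noise CV of study samples (>= 0);
#'   QC injections use half this CV (a pooled QC re-injected from one vial
#'   is more repeatable than independently prepared samples).
#' @param n_bacterial,n_chemical planted feature counts per mode.
#' @param effect_fold_72h fold change at 72 h at room temperature for
#'   planted features (> 0; trend direction is drawn per feature).
#' @param cold_attenuation fraction (in `[0, 1]`) of the room-temperature
#'   chemical effect expressed at 4 degrees C.
#' @param pres_ionization_shift global multiplicative intensity offset of
#'   preservative samples, emulating the effect of boric acid on
#'   electrospray ionisation yields.
#' @param library a `spectral_library` (or `NULL` to disable annotation
#'   planting); defaults to [demo_library()].
#' @param design optional per-experiment design list as returned by
#'   [default_design()]; when `NULL`, every experiment uses the fallback
#'   `conditions`/`time_points_h`/`growth`.
#' @param seed single integer seed; all random draws derive from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_features = 300,
                       n_annotated = 19,
                       time_points_h = c(0, 12, 24, 36, 48, 60, 72),
                       conditions = c("RT", "C4", "Pres"),
                       growth = growth_params(),
                       n_replicates = 3,
                       experiments = c("Exp1", "Exp2"),
                       ion_modes = c("positive", "negative"),
                       qc_interval = 10,
                       n_blanks = 3,
                       n_contaminants = 0,
                       blank_level = 1e-4,
                       drift_amplitude = 0.2,
                       noise_cv = 0.1,
                       n_bacterial = 12,
                       n_chemical = 7,
                       effect_fold_72h = 3,
                       cold_attenuation = 0.5,
                       pres_ionization_shift = 0.8,
                       library = demo_library(),
                       design = if (identical(experiments, c("Exp1", "Exp2")))
                         default_design() else NULL,
                       seed = 42) {
  stopifnot(n_features >= 1, n_annotated >= 0, n_annotated <= n_features,
            n_replicates >= 1, qc_interval >= 1, n_blanks >= 0,
            n_contaminants >= 0, blank_level >= 0,
            is.finite(drift_amplitude), drift_amplitude >= 0,
            drift_amplitude < 1,
            is.finite(noise_cv), noise_cv >= 0,
            n_bacterial >= 0, n_chemical >= 0,
            is.finite(effect_fold_72h), effect_fold_72h > 0,
            is.finite(cold_attenuation), cold_attenuation >= 0,
            cold_attenuation <= 1,
            is.finite(pres_ionization_shift), pres_ionization_shift > 0,
            length(seed) == 1, is.finite(seed))
  if (n_bacterial + n_chemical > n_features) {
    stop("n_bacterial + n_chemical exceeds n_features")
  }
  bad <- setdiff(ion_modes, c("positive", "negative"))
  if (length(bad)) stop("unknown ion mode(s): ", paste(bad, collapse = ", "))
  if (is.null(design)) {
    design <- stats::setNames(
      rep(list(list(conditions = conditions, time_points_h = time_points_h,
                    growth = growth)), length(experiments)),
      experiments)
  }
  if (!setequal(names(design), experiments)) {
    stop("design entries must match `experiments`")
  }
  for (e in experiments) {
    d <- design[[e]]
    bad <- setdiff(d$conditions, c("RT", "C4", "Pres"))
    if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
    tp <- d$time_points_h
    if (length(tp) < 2 || tp[1] != 0 || is.unsorted(tp, strictly = TRUE) ||
        any(!is.finite(tp)) || any(tp < 0)) {
      stop("time_points_h must be strictly increasing, finite, starting at 0")
    }
    if (is.null(d$growth)) design[[e]]$growth <- growth
    stopifnot(inherits(design[[e]]$growth, "growth_params"))
  }
  structure(list(n_features = n_features, n_annotated = n_annotated,
                 n_replicates = n_replicates, experiments = experiments,
                 ion_modes = ion_modes, qc_interval = qc_interval,
                 n_blanks = n_blanks, n_contaminants = n_contaminants,
                 blank_level = blank_level,
                 drift_amplitude = drift_amplitude, noise_cv = noise_cv,
                 n_bacterial = n_bacterial, n_chemical = n_chemical,
                 effect_fold_72h = effect_fold_72h,
                 cold_attenuation = cold_attenuation,
                 pres_ionization_shift = pres_ionization_shift,
                 library = library, design = design, seed = as.integer(seed)),
            class = "sim_config")
}

# log-normal multiplier with unit mean and the requested CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sl^2 / 2, sdlog = sl)
}

# smooth multiplicative drift as a function of injection order:
# d(u) = 1 - A * (c1 * u + (1 - c1) * u^2), u in [0, 1]; quadratic in
# order, monotone decreasing, d(0) = 1, d(1) = 1 - A
drift_curve <- function(order, n_inj, amplitude, c1) {
  u <- if (n_inj > 1) (order - 1) / (n_inj - 1) else rep(0, length(order))
  1 - amplitude * (c1 * u + (1 - c1) * u^2)
}

# per-mode feature panel: baselines, m/z, RT, planted classes and signs
sim_panel <- function(cfg, mode) {
  n <- cfg$n_features
  prefix <- if (mode == "positive") "P" else "N"
  id <- sprintf("%s%04d", prefix, seq_len(n))
  baseline <- 10^stats::runif(n, 4, 7)
  mz <- stats::runif(n, 75, 1000)
  rt <- stats::runif(n, 0, 19)
  name <- rep(NA_character_, n)
  msi <- rep(NA_character_, n)
  if (!is.null(cfg$library) && cfg$n_annotated > 0) {
    libm <- cfg$library[cfg$library$ion_mode == mode, , drop = FALSE]
    k <- min(cfg$n_annotated, nrow(libm))
    if (k > 0) {
      mz[seq_len(k)] <- libm$mz_ref[seq_len(k)]
      rt[seq_len(k)] <- libm$rt_min_ref[seq_len(k)]
      name[seq_len(k)] <- libm$name[seq_len(k)]
      msi[seq_len(k)] <- libm$msi_level[seq_len(k)]
    }
  }
  n_planted <- cfg$n_bacterial + cfg$n_chemical
  annotated <- which(!is.na(name))
  pool <- c(sample(annotated), sample(setdiff(seq_len(n), annotated)))
  planted <- pool[seq_len(n_planted)]
  class <- rep("stable", n)
  class[planted[seq_len(cfg$n_bacterial)]] <- "bacterial"
  if (cfg$n_chemical > 0) {
    class[planted[cfg$n_bacterial + seq_len(cfg$n_chemical)]] <- "chemical"
  }
  sign <- rep(0L, n)
  sign[planted] <- sample(c(1L, -1L), n_planted, replace = TRUE)
  contaminant <- rep(FALSE, n)
  if (cfg$n_contaminants > 0) {
    stable_idx <- which(class == "stable")
    contaminant[sample(stable_idx, min(cfg$n_contaminants,
                                       length(stable_idx)))] <- TRUE
  }
  data.frame(feature_id = id, mz = mz, rt_min = rt, baseline = baseline,
             class = class, sign = sign, contaminant = contaminant,
             name = name, msi_level = msi, stringsAsFactors = FALSE)
}

# condition x time multiplicative effect for one feature class
effect_multiplier <- function(class, sign, condition, time_h, cfg, g, t_max) {
  if (class == "stable" || sign == 0L) return(rep(1, length(time_h)))
  fold <- cfg$effect_fold_72h
  if (class == "bacterial") {
    if (condition != "RT") return(rep(1, length(time_h)))
    od0 <- logistic_od(0, g)
    ramp <- (logistic_od(time_h, g) - od0) / (logistic_od(t_max, g) - od0)
  } else { # chemical
    ramp <- time_h / t_max
    if (condition == "C4") ramp <- ramp * cfg$cold_attenuation
  }
  fold^(sign * ramp)
}

# one experiment x ion-mode block
sim_block <- function(cfg, experiment, mode, panel) {
  d <- cfg$design[[experiment]]
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      time_h = d$time_points_h,
                      condition = d$conditions,
                      stringsAsFactors = FALSE)
  n_study <- nrow(grid)
  t_max <- max(d$time_points_h)
  nf <- cfg$n_features

  # injection sequence: leading blanks, then a QC before every
  # `qc_interval` study injections (randomly ordered) and one closing QC
  perm <- sample(n_study)
  seq_types <- character(0)
  seq_study <- integer(0)
  for (i in seq_len(n_study)) {
    if ((i - 1) %% cfg$qc_interval == 0) {
      seq_types <- c(seq_types, "qc"); seq_study <- c(seq_study, NA)
    }
    seq_types <- c(seq_types, "study"); seq_study <- c(seq_study, perm[i])
  }
  seq_types <- c(seq_types, "qc"); seq_study <- c(seq_study, NA)
  seq_types <- c(rep("blank", cfg$n_blanks), seq_types)
  seq_study <- c(rep(NA, cfg$n_blanks), seq_study)
  n_inj <- length(seq_types)
  order <- seq_len(n_inj)

  short <- c(positive = "pos", negative = "neg")[[mode]]
  inj_id <- sprintf("%s_%s_%03d", experiment, short, order)
  injections <- data.frame(
    injection_id = inj_id, order = order, type = seq_types,
    condition = NA_character_, time_h = NA_real_, replicate = NA_integer_,
    experiment = experiment, ion_mode = mode, stringsAsFactors = FALSE)
  st <- which(seq_types == "study")
  injections$condition[st] <- grid$condition[seq_study[st]]
  injections$time_h[st] <- grid$time_h[seq_study[st]]
  injections$replicate[st] <- grid$replicate[seq_study[st]]

  # drift-free, noise-free expected study intensities
  expected_study <- matrix(NA_real_, nf, n_study,
                           dimnames = list(panel$feature_id, NULL))
  for (f in seq_len(nf)) {
    row <- rep(1, n_study)
    for (cond in unique(grid$condition)) {
      sel <- grid$condition == cond
      row[sel] <- effect_multiplier(panel$class[f], panel$sign[f], cond,
                                    grid$time_h[sel], cfg, d$growth, t_max)
    }
    expected_study[f, ] <- panel$baseline[f] * row
  }
  pres <- grid$condition == "Pres"
  expected_study[, pres] <- expected_study[, pres] * cfg$pres_ionization_shift

  c1 <- stats::runif(1, 0.3, 0.7)
  drift <- drift_curve(order, n_inj, cfg$drift_amplitude, c1)

  m <- matrix(0, nf, n_inj, dimnames = list(panel$feature_id, inj_id))
  for (j in seq_len(n_inj)) {
    if (seq_types[j] == "study") {
      mu <- expected_study[, seq_study[j]]
      m[, j] <- mu * drift[j] * rlnorm_cv(nf, cfg$noise_cv)
    } else if (seq_types[j] == "qc") {
      m[, j] <- panel$baseline * drift[j] * rlnorm_cv(nf, cfg$noise_cv / 2)
    } else { # blank
      level <- ifelse(panel$contaminant, 0.8 * panel$baseline,
                      cfg$blank_level * panel$baseline)
      m[, j] <- level * rlnorm_cv(nf, 0.3)
    }
  }

  tab <- feature_table(m, panel[, c("feature_id", "mz", "rt_min")],
                       injections)
  list(table = tab,
       truth = list(drift = data.frame(order = order, divisor = drift),
                    drift_coef = c(c1 = c1, amplitude = cfg$drift_amplitude),
                    expected = expected_study[, seq_study[st], drop = FALSE],
                    study_injection_id = inj_id[st]))
}

#' Simulate the full synthetic study
#'
#' Generates one feature table per experiment x ionisation-mode block, the
#' turbidity curves, and a ground-truth ledger recording everything
#' planted (feature classes and trend directions, per-block drift curves,
#' drift-free expected intensities). The feature panel is drawn once per
#' ionisation mode and shared across experiments, so per-metabolite
#' evidence can be combined between experiments as in a real replicated
#' study.
#'
#' @param cfg a [sim_config()].
#' @return List with elements:
#'   \describe{
#'     \item{tables}{named list of [feature_table()]s, one per
#'       `<experiment>.<ion_mode>` block;}
#'     \item{truth}{ground-truth ledger: `features` (per-mode panel with
#'       `class`, `sign`, `contaminant`, planted `name`), `trends`
#'       (per feature x condition expected monotone-trend flag), `blocks`
#'       (per-block drift curve and expected study intensities), and the
#'       echoed `config`;}
#'     \item{turbidity}{tidy triplicate OD620 per experiment x condition x
#'       time.}
#'   }
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  panels <- lapply(stats::setNames(cfg$ion_modes, cfg$ion_modes),
                   function(mode) sim_panel(cfg, mode))

  tables <- list()
  blocks <- list()
  for (e in cfg$experiments) {
    for (mode in cfg$ion_modes) {
      key <- paste(e, mode, sep = ".")
      blk <- sim_block(cfg, e, mode, panels[[mode]])
      tables[[key]] <- blk$table
      blocks[[key]] <- blk$truth
    }
  }

  turbidity <- do.call(rbind, lapply(cfg$experiments, function(e) {
    d <- cfg$design[[e]]
    do.call(rbind, lapply(d$conditions, function(cond) {
      g <- if (cond == "RT") d$growth else
        growth_params(od_baseline = d$growth$od_baseline,
                      od_max = d$growth$od_baseline + 0.01,
                      lag_h = 1e6, rate_per_h = d$growth$rate_per_h)
      sub_seed <- (cfg$seed + 7919 * match(e, cfg$experiments) +
                     31 * match(cond, c("RT", "C4", "Pres"))) %% 2147483647L
      tc <- simulate_turbidity(d$time_points_h, g, cfg$n_replicates,
                               noise_sd = 0.02, seed = sub_seed)
      data.frame(experiment = e, condition = cond, tc,
                 stringsAsFactors = FALSE)
    }))
  }))
  # simulate_turbidity reseeds; restore nothing (all table draws are done)

  features <- do.call(rbind, lapply(cfg$ion_modes, function(mode) {
    data.frame(ion_mode = mode, panels[[mode]], stringsAsFactors = FALSE)
  }))
  rownames(features) <- NULL

  trends <- do.call(rbind, lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    trending <- c(
      RT = f$class %in% c("bacterial", "chemical"),
      C4 = f$class == "chemical" && cfg$cold_attenuation > 0,
      Pres = f$class == "chemical")
    data.frame(feature_id = f$feature_id, ion_mode = f$ion_mode,
               condition = names(trending), trending = unname(trending),
               sign = ifelse(unname(trending), f$sign, 0L),
               stringsAsFactors = FALSE)
  }))
  rownames(trends) <- NULL

  list(tables = tables,
       truth = list(features = features, trends = trends, blocks = blocks,
                    config = cfg),
       turbidity = turbidity)
}

#' Simulate one experiment
#'
#' Convenience wrapper around [simulate_study()] returning only the blocks
#' of a single experiment (one feature table per ionisation mode) together
#' with the full ground-truth ledger.
#'
#' @param cfg a [sim_config()].
#' @param experiment experiment label (default: first configured).
#' @return List with `tables` (per ion mode) and `truth`.
#' @export
simulate_experiment <- function(cfg, experiment = cfg$experiments[1]) {
  stopifnot(experiment %in% cfg$experiments)
  sim <- simulate_study(cfg)
  keys <- paste(experiment, cfg$ion_modes, sep = ".")
  list(tables = stats::setNames(sim$tables[keys], cfg$ion_modes),
       truth = sim$truth)
}

#' Write a simulated study to a directory
#'
#' Writes every block's intensity and injection-metadata files, the
#' ground-truth feature ledger, the expected trend flags and the turbidity
#' table as tab-separated text.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(sim$tables)) {
    write_feature_table(sim$tables[[key]],
                        file.path(dir, paste0(key, "_intensities.tsv")),
                        file.path(dir, paste0(key, "_injections.tsv")))
  }
  write_results(sim$truth$features, file.path(dir, "ground_truth_features.tsv"))
  write_results(sim$truth$trends, file.path(dir, "ground_truth_trends.tsv"))
  write_results(sim$turbidity, file.path(dir, "turbidity.tsv"))
  invisible(dir)
}
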