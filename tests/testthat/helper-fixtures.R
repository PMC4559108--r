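# Small constructors used across the suite.

# Build a feature table directly from a matrix and run-sequence types.
# types: character vector over injections ("study", "qc", "blank");
# study injections get condition/time/replicate from the parallel vectors
# (recycled NA for non-study).
make_ft <- function(m, types,
                    condition = NA_character_, time_h = NA_real_,
                    replicate = NA_integer_,
                    experiment = "Exp1", ion_mode = "positive",
                    mz = NULL, rt_min = NULL) {
  n_inj <- ncol(m)
  nf <- nrow(m)
  dimnames(m) <- NULL
  stopifnot(length(types) == n_inj)
  fill <- function(x, default) {
    x <- rep_len(x, n_inj)
    x[types != "study"] <- default
    x
  }
  injections <- data.frame(
    injection_id = sprintf("inj%03d", seq_len(n_inj)),
    order = seq_len(n_inj), type = types,
    condition = fill(condition, NA_character_),
    time_h = fill(time_h, NA_real_),
    replicate = fill(replicate, NA_integer_),
    experiment = experiment, ion_mode = ion_mode,
    stringsAsFactors = FALSE)
  features <- data.frame(
    feature_id = sprintf("F%03d", seq_len(nf)),
    mz = if (is.null(mz)) seq(100, 900, length.out = nf) else mz,
    rt_min = if (is.null(rt_min)) seq(1, 18, length.out = nf) else rt_min,
    stringsAsFactors = FALSE)
  feature_table(m, features, injections)
}

# A single-condition time-course block: n_rep replicates at each time,
# leading QC, interleaved QCs, trailing QC; intensity = baseline (matrix
# `values` features x study-samples supplied by caller).
make_timecourse_ft <- function(values, time_h, n_rep,
                               condition = "RT", qc_value = NULL, ...) {
  n_study <- length(time_h) * n_rep
  stopifnot(ncol(values) == n_study)
  qc_value <- if (is.null(qc_value)) rowMeans(values) else qc_value
  types <- c("qc", rep("study", n_study), "qc")
  m <- cbind(qc_value, values, qc_value)
  make_ft(m, types,
          condition = condition,
          time_h = c(NA, rep(time_h, each = n_rep), NA),
          replicate = c(NA, rep(seq_len(n_rep), length(time_h)), NA), ...)
}

# Correlation-record row for classification tests.
make_record <- function(feature_id, condition, significant, sign = "+",
                        experiment = "Exp1", rho = NULL, q = NULL) {
  rho <- if (!is.null(rho)) rho else
    if (significant) ifelse(sign == "+", 0.9, -0.9) else 0.1
  data.frame(feature_id = feature_id, experiment = experiment,
             condition = condition, ion_mode = "positive",
             rho = rho, p = if (significant) 1e-5 else 0.5,
             q = if (!is.null(q)) q else if (significant) 1e-4 else 0.8,
             significant = significant,
             sign = if (significant) sign else "ns",
             stringsAsFactors = FALSE)
}

# Quadratic-time reference implementation of BH (independent oracle):
# q_i = min over j with p_j >= p_i of m * p_j / #{k: p_k <= p_j}.
bh_reference <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i])
    ranks <- vapply(cand, function(j) sum(p <= p[j]), numeric(1))
    min(1, min(m * p[cand] / ranks))
  }, numeric(1))
}

# small default simulation for fast tests (one mode, overridable)
quick_cfg <- function(...) {
  defaults <- list(n_features = 40, n_annotated = 0, library = NULL,
                   ion_modes = "positive", n_bacterial = 3, n_chemical = 2,
                   n_blanks = 2, seed = 101)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
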