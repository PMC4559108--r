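#' Robust metabolite selection across experiments
#'
#' A metabolite is selected iff (a) its room-temperature correlation with
#' storage duration is significant, with the same sign, in every
#' experiment where it was measured, and (b) its significance status
#' (significant vs ns) at 4 degrees C is identical across the experiments
#' where it was measured. Metabolites present in a single experiment are
#' evaluated on that experiment alone. Discordance in the preservative
#' condition does not block selection (not every experiment has a
#' preservative arm).
#'
#' Metabolites failing robustness but showing trends judged meaningful
#' can be force-included through an explicit `allow_list`; they are never
#' auto-included.
#'
#' @param records correlation records across experiments (row-bound
#'   output of [correlate_with_time()] / [screen_conditions()]).
#' @param allow_list feature ids to include regardless of the criteria.
#' @return List with `ids` (selected feature ids, allow-listed ones
#'   included) and `report` (per-feature criteria evaluation).
#' @export
select_robust <- function(records, allow_list = character(0)) {
  stopifnot(is.data.frame(records))
  ids <- unique(records$feature_id)
  rows <- lapply(ids, function(id) {
    r <- records[records$feature_id == id, , drop = FALSE]
    rt <- r[r$condition == "RT", , drop = FALSE]
    c4 <- r[r$condition == "C4", , drop = FALSE]
    rt_all_sig <- nrow(rt) > 0 && all(rt$significant)
    rt_consistent <- rt_all_sig && length(unique(rt$sign)) == 1
    c4_concordant <- nrow(c4) == 0 ||
      length(unique(c4$significant)) == 1
    data.frame(feature_id = id,
               n_experiments = length(unique(r$experiment)),
               rt_all_significant = rt_all_sig,
               rt_sign_consistent = rt_consistent,
               c4_status_concordant = c4_concordant,
               selected = rt_consistent && c4_concordant,
               allow_listed = id %in% allow_list,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  missing_allow <- setdiff(allow_list, ids)
  if (length(missing_allow)) {
    warning("allow-listed id(s) absent from records: ",
            paste(missing_allow, collapse = ", "))
  }
  list(ids = report$feature_id[report$selected | report$allow_listed],
       report = report)
}

condition_status <- function(r, condition) {
  sub <- r[r$condition == condition, , drop = FALSE]
  if (!nrow(sub)) {
    return(list(measured = FALSE, significant = FALSE, sign = NA_character_))
  }
  sig <- any(sub$significant)
  sgn <- unique(sub$sign[sub$significant])
  list(measured = TRUE, significant = sig,
       sign = if (sig && length(sgn) == 1) sgn else
         if (sig) "conflict" else NA_character_)
}

#' Classify one metabolite as bacterial, chemical or indeterminate
#'
#' Pure function of the per-condition significance pattern: a
#' significant correlation with storage duration only at room
#' temperature indicates an impact of bacterial overgrowth (bacteria do
#' not grow at 4 degrees C or with preservative), whereas a significant
#' correlation at room temperature and at 4 degrees C and/or with
#' preservative indicates chemical instability in solution. Any other
#' pattern, and any conflict of trend signs between significant
#' conditions or experiments, yields `stable_or_indeterminate` with an
#' explicit reason.
#'
#' @param records correlation records of a single metabolite (possibly
#'   several experiments and conditions).
#' @param onsets optional onset-time table (see [onset_table()]) from
#'   which per-condition onset times are attached (earliest across
#'   experiments).
#' @return One-row data frame: `feature_id`, `class`, `sign`, `rt_sig`,
#'   `c4_sig`, `pres_sig`, `onset_rt_h`, `onset_c4_h`, `onset_pres_h`,
#'   `experiments`, `reason`.
#' @export
classify <- function(records, onsets = NULL) {
  stopifnot(is.data.frame(records))
  id <- unique(records$feature_id)
  if (length(id) != 1) stop("records must concern a single metabolite")
  rt <- condition_status(records, "RT")
  c4 <- condition_status(records, "C4")
  pres <- condition_status(records, "Pres")

  signs <- c(rt$sign, c4$sign, pres$sign)
  conflict <- any(signs == "conflict", na.rm = TRUE) ||
    length(unique(stats::na.omit(signs))) > 1

  if (!rt$significant) {
    class <- "stable_or_indeterminate"
    reason <- if (c4$significant || pres$significant) {
      "significant at C4/Pres but not at RT"
    } else {
      "no significant correlation"
    }
  } else if (conflict) {
    class <- "stable_or_indeterminate"
    reason <- "conflicting trend signs between conditions or experiments"
  } else if (c4$significant || pres$significant) {
    class <- "chemical"
    reason <- ""
  } else {
    class <- "bacterial"
    reason <- ""
  }

  onset_for <- function(cond) {
    if (is.null(onsets)) return(NA_real_)
    o <- onsets[onsets$feature_id == id & onsets$condition == cond,
                "onset_h"]
    o <- o[!is.na(o)]
    if (length(o)) min(o) else NA_real_
  }
  data.frame(feature_id = id, class = class,
             sign = if (class %in% c("bacterial", "chemical")) rt$sign
                    else NA_character_,
             rt_sig = rt$significant, c4_sig = c4$significant,
             pres_sig = pres$significant,
             onset_rt_h = onset_for("RT"), onset_c4_h = onset_for("C4"),
             onset_pres_h = onset_for("Pres"),
             experiments = paste(sort(unique(records$experiment)),
                                 collapse = ";"),
             reason = reason, stringsAsFactors = FALSE)
}

#' Stability calls for all robustly selected metabolites
#'
#' Runs [select_robust()] and then [classify()] on each selected (or
#' allow-listed) metabolite.
#'
#' @param records correlation records across experiments and conditions.
#' @param onsets optional onset table ([onset_table()] output, possibly
#'   row-bound across blocks).
#' @param allow_list feature ids to force-include (see
#'   [select_robust()]).
#' @return Data frame of stability calls (one row per selected
#'   metabolite), plus the selection report as attribute `"selection"`.
#' @export
classify_calls <- function(records, onsets = NULL,
                           allow_list = character(0)) {
  sel <- select_robust(records, allow_list)
  calls <- lapply(sel$ids, function(id) {
    classify(records[records$feature_id == id, , drop = FALSE], onsets)
  })
  out <- if (length(calls)) do.call(rbind, calls) else
    classify_empty()
  rownames(out) <- NULL
  attr(out, "selection") <- sel$report
  out
}

classify_empty <- function() {
  data.frame(feature_id = character(0), class = character(0),
             sign = character(0), rt_sig = logical(0), c4_sig = logical(0),
             pres_sig = logical(0), onset_rt_h = numeric(0),
             onset_c4_h = numeric(0), onset_pres_h = numeric(0),
             experiments = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

#' Summarise stability calls
#'
#' Deterministic counts per class, and (when the correlation records are
#' supplied) the number of metabolites measured per experiment together
#' with the number common to all experiments.
#'
#' @param calls output of [classify_calls()].
#' @param records optional correlation records used to count metabolites
#'   per experiment.
#' @return List with `class_counts` (data frame class/n) and
#'   `experiment_counts` (data frame, or `NULL` without `records`;
#'   the `"common"` row counts metabolites present in every experiment).
#' @export
summarize_calls <- function(calls, records = NULL) {
  classes <- c("bacterial", "chemical", "stable_or_indeterminate")
  class_counts <- data.frame(
    class = classes,
    n = vapply(classes, function(cl) sum(calls$class == cl), integer(1)),
    stringsAsFactors = FALSE)
  rownames(class_counts) <- NULL
  experiment_counts <- NULL
  if (!is.null(records) && nrow(records)) {
    sets <- lapply(split(records$feature_id, records$experiment), unique)
    experiment_counts <- data.frame(
      experiment = c(names(sets), "common"),
      n = c(vapply(sets, length, integer(1)),
            length(Reduce(intersect, sets))),
      stringsAsFactors = FALSE)
    rownames(experiment_counts) <- NULL
  }
  list(class_counts = class_counts, experiment_counts = experiment_counts)
}
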