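#' Feature table: intensities plus feature and injection metadata
#'
#' The universal currency of the pipeline: an LC-MS peak table for one
#' experiment x ionisation-mode block. Intensities are stored as a
#' features x injections matrix; feature metadata carry the accurate mass
#' and retention time used for annotation; injection metadata carry the
#' run design (injection order, sample type, storage condition, storage
#' duration, replicate, experiment, ionisation mode).
#'
#' @param intensities numeric matrix, features in rows and injections in
#'   columns. Row names (if any) must agree with `features$feature_id` and
#'   column names with `injections$injection_id`.
#' @param features data frame with columns `feature_id`, `mz` (Th) and
#'   `rt_min` (minutes), one row per intensity-matrix row.
#' @param injections data frame with columns `injection_id`, `order`
#'   (unique positive integers), `type` (`"study"`, `"qc"` or `"blank"`),
#'   `condition` (`"RT"`, `"C4"`, `"Pres"` or `NA` for non-study
#'   injections), `time_h`, `replicate`, `experiment` and `ion_mode`, one
#'   row per intensity-matrix column.
#'
#' @return An object of class `feature_table` with elements `intensities`,
#'   `features` and `injections`, injections sorted by `order`.
#' @export
feature_table <- function(intensities, features, injections) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix (features x injections)")
  }
  features <- as.data.frame(features)
  injections <- as.data.frame(injections)

  need_feat <- c("feature_id", "mz", "rt_min")
  miss <- setdiff(need_feat, names(features))
  if (length(miss)) {
    stop("feature metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  need_inj <- c("injection_id", "order", "type", "condition", "time_h",
                "replicate", "experiment", "ion_mode")
  miss <- setdiff(need_inj, names(injections))
  if (length(miss)) {
    stop("injection metadata lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(features) != nrow(intensities)) {
    stop("feature metadata rows (", nrow(features),
         ") != intensity rows (", nrow(intensities), ")")
  }
  if (nrow(injections) != ncol(intensities)) {
    stop("injection metadata rows (", nrow(injections),
         ") != intensity columns (", ncol(intensities), ")")
  }

  features$feature_id <- as.character(features$feature_id)
  injections$injection_id <- as.character(injections$injection_id)
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature_id: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]),
               collapse = ", "))
  }
  if (anyDuplicated(injections$injection_id)) {
    stop("duplicate injection_id: ",
         paste(unique(injections$injection_id[duplicated(injections$injection_id)]),
               collapse = ", "))
  }
  if (!is.null(rownames(intensities)) &&
      !identical(rownames(intensities), features$feature_id)) {
    stop("intensity row names disagree with features$feature_id")
  }
  if (!is.null(colnames(intensities)) &&
      !identical(colnames(intensities), injections$injection_id)) {
    stop("intensity column names disagree with injections$injection_id")
  }

  if (anyDuplicated(injections$order)) {
    stop("injection orders are not unique")
  }
  if (any(!is.finite(injections$order)) || any(injections$order <= 0)) {
    stop("injection orders must be positive and finite")
  }
  bad_type <- setdiff(unique(injections$type), c("study", "qc", "blank"))
  if (length(bad_type)) {
    stop("unknown injection type(s): ", paste(bad_type, collapse = ", "))
  }
  study <- injections$type == "study"
  if (any(study & (is.na(injections$condition) | is.na(injections$time_h)))) {
    bad <- injections$injection_id[study &
      (is.na(injections$condition) | is.na(injections$time_h))]
    stop("study injection(s) without condition/time_h: ",
         paste(bad, collapse = ", "))
  }
  bad_cond <- setdiff(unique(injections$condition[study]), c("RT", "C4", "Pres"))
  if (length(bad_cond)) {
    stop("unknown condition(s): ", paste(bad_cond, collapse = ", "))
  }
  neg <- which(intensities < 0 & !is.na(intensities), arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative intensity at feature row ", neg[1, 1],
         ", injection column ", neg[1, 2])
  }

  ord <- order(injections$order)
  injections <- injections[ord, , drop = FALSE]
  intensities <- intensities[, ord, drop = FALSE]
  rownames(intensities) <- features$feature_id
  colnames(intensities) <- injections$injection_id
  rownames(features) <- NULL
  rownames(injections) <- NULL

  structure(list(intensities = intensities, features = features,
                 injections = injections),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  inj <- x$injections
  cat("feature_table: ", nrow(x$intensities), " features x ",
      ncol(x$intensities), " injections\n", sep = "")
  cat("  study/qc/blank: ", sum(inj$type == "study"), "/",
      sum(inj$type == "qc"), "/", sum(inj$type == "blank"), "\n", sep = "")
  cat("  experiment(s): ", paste(unique(inj$experiment), collapse = ", "),
      "; ion mode(s): ", paste(unique(inj$ion_mode), collapse = ", "), "\n",
      sep = "")
  conds <- unique(stats::na.omit(inj$condition))
  if (length(conds)) {
    cat("  conditions: ", paste(conds, collapse = ", "),
        "; time points (h): ",
        paste(sort(unique(stats::na.omit(inj$time_h))), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Subset a feature table
#'
#' @param t a [feature_table()].
#' @param features character vector of feature ids or logical/integer index
#'   over feature rows; `NULL` keeps all.
#' @param injections character vector of injection ids or logical/integer
#'   index over injections; `NULL` keeps all.
#' @return The subset `feature_table`.
#' @export
ft_subset <- function(t, features = NULL, injections = NULL) {
  stopifnot(inherits(t, "feature_table"))
  fi <- seq_len(nrow(t$intensities))
  if (!is.null(features)) {
    fi <- if (is.character(features)) {
      match(features, t$features$feature_id)
    } else {
      fi[features]
    }
    if (anyNA(fi)) stop("unknown feature id(s) in subset")
  }
  ji <- seq_len(ncol(t$intensities))
  if (!is.null(injections)) {
    ji <- if (is.character(injections)) {
      match(injections, t$injections$injection_id)
    } else {
      ji[injections]
    }
    if (anyNA(ji)) stop("unknown injection id(s) in subset")
  }
  feature_table(t$intensities[fi, ji, drop = FALSE],
                t$features[fi, , drop = FALSE],
                t$injections[ji, , drop = FALSE])
}

#' Select injections of one type
#'
#' Convenience selectors for the three injection classes of a run sequence.
#'
#' @param t a [feature_table()].
#' @return Logical vector over injections (in order).
#' @export
is_study <- function(t) t$injections$type == "study"

#' @rdname is_study
#' @export
is_qc <- function(t) t$injections$type == "qc"

#' @rdname is_study
#' @export
is_blank <- function(t) t$injections$type == "blank"
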