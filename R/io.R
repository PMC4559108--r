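#' Read a feature table from delimited text
#'
#' The on-disk layout follows common XCMS-export conventions: one
#' intensities file with features as rows (columns `feature_id`, `mz`,
#' `rt_min`, then one column per injection) and one injection-metadata file
#' (columns `injection_id`, `order`, `type`, `condition`, `time_h`,
#' `replicate`, `experiment`, `ion_mode`). Missing intensities are encoded
#' `NA` and kept missing (not zero) downstream.
#'
#' @param intensity_path path to the intensities file.
#' @param metadata_path path to the injection-metadata file.
#' @param sep field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the first header line.
#' @return A validated [feature_table()], injections sorted by run order.
#' @export
read_feature_table <- function(intensity_path, metadata_path, sep = NULL) {
  for (p in c(intensity_path, metadata_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  sep_i <- if (is.null(sep)) detect_sep(intensity_path) else sep
  sep_m <- if (is.null(sep)) detect_sep(metadata_path) else sep
  ints <- utils::read.table(intensity_path, header = TRUE, sep = sep_i,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            na.strings = "NA", quote = "\"",
                            comment.char = "")
  meta <- utils::read.table(metadata_path, header = TRUE, sep = sep_m,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            na.strings = "NA", quote = "\"",
                            comment.char = "")
  need <- c("feature_id", "mz", "rt_min")
  miss <- setdiff(need, names(ints))
  if (length(miss)) {
    stop("intensities file lacks column(s): ", paste(miss, collapse = ", "))
  }
  inj_cols <- setdiff(names(ints), need)
  unknown <- setdiff(inj_cols, as.character(meta$injection_id))
  if (length(unknown)) {
    stop("intensity column(s) with no metadata row: ",
         paste(unknown, collapse = ", "))
  }
  absent <- setdiff(as.character(meta$injection_id), inj_cols)
  if (length(absent)) {
    stop("metadata references unknown injection_id: ",
         paste(absent, collapse = ", "))
  }
  m <- as.matrix(ints[, as.character(meta$injection_id), drop = FALSE])
  storage.mode(m) <- "double"
  feature_table(m, ints[, need], meta)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Write a feature table as two delimited files
#'
#' Inverse of [read_feature_table()]: lossless for finite values (values
#' are written with full `.17g` precision).
#'
#' @param t a [feature_table()].
#' @param intensity_path,metadata_path output paths.
#' @param sep field delimiter (default tab).
#' @return Invisibly, the two paths.
#' @export
write_feature_table <- function(t, intensity_path, metadata_path, sep = "\t") {
  stopifnot(inherits(t, "feature_table"))
  m <- t$intensities
  out <- data.frame(t$features,
                    as.data.frame(formatC(m, format = "g", digits = 17),
                                  check.names = FALSE,
                                  stringsAsFactors = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  # formatC leaves NA as "NA"; blank-pad artefacts are trimmed
  out[, -(1:3)] <- lapply(out[, -(1:3), drop = FALSE], trimws)
  write_delim(out, intensity_path, sep)
  write_delim(t$injections, metadata_path, sep)
  invisible(c(intensity_path, metadata_path))
}

#' Read a spectral library
#'
#' A spectral library lists reference metabolites with the ion m/z expected
#' in each ionisation mode, the reference retention time, and the MSI
#' (Metabolomics Standards Initiative) identification-confidence level.
#' Required columns: `name`, `mz_ref` (Th), `ion_mode`, `rt_min_ref`,
#' `msi_level` (`"ID"`, `"Putative A"` or `"Putative C"`).
#'
#' @param path delimited text file (tab or comma separated).
#' @param sep delimiter; `NULL` auto-detects.
#' @return A data frame of class `spectral_library`.
#' @export
read_library <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  lib <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  need <- c("name", "mz_ref", "ion_mode", "rt_min_ref", "msi_level")
  miss <- setdiff(need, names(lib))
  if (length(miss)) {
    stop("library lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(!nzchar(lib$name) | is.na(lib$name))) stop("empty metabolite name")
  if (any(!is.finite(lib$mz_ref) | lib$mz_ref <= 0)) {
    stop("library m/z must be positive")
  }
  class(lib) <- c("spectral_library", "data.frame")
  lib
}

#' Write a result table as delimited text
#'
#' Generic writer for the pipeline's record tables (correlation records,
#' filter reports, stability calls, ...). An empty record list yields a
#' header-only file.
#'
#' @param records data frame (possibly zero rows).
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @return Invisibly, `path`.
#' @export
write_results <- function(records, path, sep = "\t") {
  write_delim(as.data.frame(records), path, sep)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path delimited text file.
#' @param sep delimiter; `NULL` auto-detects.
#' @return A data frame.
#' @export
read_results <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, quote = "\"",
                    comment.char = "", na.strings = "NA")
}

write_delim <- function(df, path, sep) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                       col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ", conditionMessage(ok))
  invisible(path)
}
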