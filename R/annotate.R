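#' Relative mass error in parts per million
#'
#' @param mz_obs observed m/z (Th).
#' @param mz_ref reference m/z (Th, > 0).
#' @return `(mz_obs - mz_ref) / mz_ref * 1e6` (signed; vectorised).
#' @export
ppm_error <- function(mz_obs, mz_ref) {
  if (any(!is.finite(mz_ref) | mz_ref <= 0)) {
    stop("mz_ref must be positive and finite")
  }
  (mz_obs - mz_ref) / mz_ref * 1e6
}

#' Annotate features against a spectral library
#'
#' Matches every feature of a table to the library entries of the same
#' ionisation mode by accurate mass (within `ppm_tol`, symmetric) and
#' retention time (within `rt_tol_min`). Every matching (feature, entry)
#' pair is emitted; multiple matches are allowed and ranked per feature
#' by |ppm error|, ties broken by |RT error|. Features without any match
#' remain unannotated (absent from the result). MSI evidence levels are
#' carried verbatim from the library.
#'
#' @param t a [feature_table()] of a single ionisation mode.
#' @param lib a `spectral_library` (see [read_library()]).
#' @param ppm_tol mass tolerance in ppm (default 5).
#' @param rt_tol_min retention-time tolerance in minutes (default 0.5,
#'   conservative for a 19-min gradient).
#' @return Data frame with columns `feature_id`, `name`, `ppm_error`,
#'   `rt_error_min`, `msi_level`, `ion_mode`, `rank` (1 = best match for
#'   that feature). Zero rows (with a warning) for an empty library.
#' @export
annotate <- function(t, lib, ppm_tol = 5, rt_tol_min = 0.5) {
  stopifnot(inherits(t, "feature_table"), ppm_tol > 0, rt_tol_min >= 0)
  mode <- unique(t$injections$ion_mode)
  if (length(mode) != 1) stop("table mixes ionisation modes")
  empty <- data.frame(feature_id = character(0), name = character(0),
                      ppm_error = numeric(0), rt_error_min = numeric(0),
                      msi_level = character(0), ion_mode = character(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  libm <- lib[lib$ion_mode == mode, , drop = FALSE]
  if (nrow(libm) == 0) {
    warning("no library entries for ion mode ", mode)
    return(empty)
  }
  fe <- t$features
  hits <- lapply(seq_len(nrow(fe)), function(i) {
    dppm <- ppm_error(fe$mz[i], libm$mz_ref)
    drt <- fe$rt_min[i] - libm$rt_min_ref
    ok <- abs(dppm) <= ppm_tol & abs(drt) <= rt_tol_min
    if (!any(ok)) return(NULL)
    out <- data.frame(feature_id = fe$feature_id[i], name = libm$name[ok],
                      ppm_error = dppm[ok], rt_error_min = drt[ok],
                      msi_level = libm$msi_level[ok], ion_mode = mode,
                      stringsAsFactors = FALSE)
    out <- out[order(abs(out$ppm_error), abs(out$rt_error_min)), ,
               drop = FALSE]
    out$rank <- seq_len(nrow(out))
    out
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) return(empty)
  res <- do.call(rbind, hits)
  rownames(res) <- NULL
  res
}
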