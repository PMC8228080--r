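#' Flag outlier fMRI volumes from motion and intensity traces
#'
#' A volume is flagged if its scalar motion from the previous volume exceeds
#' 2 mm, or if its mean-intensity difference from the previous volume
#' exceeds 2.5 times the standard deviation of mean intensity over the whole
#' run. Both rules are strict inequalities ("larger than"), and the first
#' volume is never flagged (it has no predecessor). The run SD is computed
#' in a single pass over all volumes, outliers included.
#'
#' @param motion a `"motion_trace"` (or any list with numeric
#'   `displacement` and `mean_intensity` of equal length >= 2).
#' @param motion_threshold_mm motion flagging threshold (default 2 mm).
#' @param intensity_threshold_sd intensity threshold in run SDs
#'   (default 2.5).
#' @return Object of class `"qc_report"`: list with logical `motion_flags`,
#'   `intensity_flags`, `outlier_flags` (elementwise OR) and `n_volumes`.
#' @export
flag_outlier_volumes <- function(motion, motion_threshold_mm = 2,
                                 intensity_threshold_sd = 2.5) {
  d <- motion$displacement
  mi <- motion$mean_intensity
  stopifnot(is.numeric(d), is.numeric(mi), length(d) == length(mi))
  n <- length(d)
  if (n < 2L) stop("at least 2 volumes are required")
  motion_flags <- c(FALSE, d[-1L] > motion_threshold_mm)
  run_sd <- sd(mi)
  diffs <- abs(diff(mi))
  intensity_flags <- c(FALSE, diffs > intensity_threshold_sd * run_sd)
  structure(list(motion_flags = motion_flags,
                 intensity_flags = intensity_flags,
                 outlier_flags = motion_flags | intensity_flags,
                 n_volumes = n),
            class = "qc_report")
}

#' Decide run exclusion from a QC report
#'
#' A run is excluded if more than 20% of all its volumes are flagged as
#' outliers, or if more than 30% of the volumes carrying any single stimulus
#' condition are flagged. Both are strict inequalities ("more than"), so a
#' run at exactly 20%/30% is kept. Volumes whose condition label is `NA` or
#' `""` count toward the overall fraction only.
#'
#' @param report a `"qc_report"` from [flag_outlier_volumes()].
#' @param condition_labels per-volume condition labels (length =
#'   `report$n_volumes`).
#' @param overall_threshold overall flagged fraction above which the run is
#'   excluded (default 0.20).
#' @param condition_threshold per-condition flagged fraction above which the
#'   run is excluded (default 0.30).
#' @return The report augmented with `overall_fraction`,
#'   `per_condition_fraction` (named vector) and logical `excluded`.
#' @export
decide_run_exclusion <- function(report, condition_labels,
                                 overall_threshold = 0.20,
                                 condition_threshold = 0.30) {
  stopifnot(inherits(report, "qc_report"))
  if (length(condition_labels) != report$n_volumes)
    stop("condition_labels must have one entry per volume")
  flags <- report$outlier_flags
  overall <- mean(flags)
  keep <- !is.na(condition_labels) & condition_labels != ""
  conds <- unique(condition_labels[keep])
  frac <- setNames(numeric(length(conds)), conds)
  for (cond in conds) {
    in_cond <- keep & condition_labels == cond
    if (!any(in_cond)) {
      warning("condition '", cond, "' labels no volumes; skipped")
      frac[cond] <- NA_real_
      next
    }
    frac[cond] <- mean(flags[in_cond])
  }
  report$overall_fraction <- overall
  report$per_condition_fraction <- frac
  report$excluded <- overall > overall_threshold ||
    any(frac > condition_threshold, na.rm = TRUE)
  report
}

#' Spike regressors for flagged volumes
#'
#' One indicator column per flagged outlier volume, for use as nuisance
#' regressors in the first-level GLM.
#'
#' @param report a `"qc_report"`.
#' @return A `n_volumes x n_flagged` 0/1 matrix (zero columns if no volume
#'   is flagged).
#' @export
spike_regressors <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  idx <- which(report$outlier_flags)
  out <- matrix(0, report$n_volumes, length(idx))
  for (k in seq_along(idx)) out[idx[k], k] <- 1
  if (length(idx)) colnames(out) <- paste0("spike_vol", idx)
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_volumes, "volumes,", sum(x$outlier_flags),
      "flagged\n")
  if (!is.null(x$excluded))
    cat("  overall fraction:", format(x$overall_fraction, digits = 3),
        " excluded:", x$excluded, "\n")
  invisible(x)
}
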