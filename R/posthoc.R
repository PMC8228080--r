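#' Per-ROI two-sample group t-tests
#'
#' Pooled-variance (Student) two-sample t per (ROI, contrast), signed TR
#' minus DD so positive t means higher activation in typical readers, with
#' uncorrected two-sided p-values. The pooled form reproduces the study's
#' df = n1 + n2 - 2 = 42 for 22 + 22 subjects.
#'
#' @param features subjects x ROIs x contrasts array.
#' @param labels +1 (DD) / -1 (TR).
#' @return Data frame with one row per (ROI, contrast): `roi`, `contrast`,
#'   `t`, `df`, `p`.
#' @export
roi_group_ttests <- function(features, labels) {
  check_features(features)
  y <- check_labels(labels, dim(features)[1L])
  d <- dim(features)
  dn <- dimnames(features)
  rois <- if (is.null(dn[[2L]])) sprintf("roi%03d", seq_len(d[2L]))
          else dn[[2L]]
  contrasts <- if (is.null(dn[[3L]])) paste0("contrast", seq_len(d[3L]))
               else dn[[3L]]
  tr <- y == -1; dd <- y == 1
  if (sum(tr) < 2L || sum(dd) < 2L) stop("each group needs n >= 2")
  out <- expand.grid(roi = rois, contrast = contrasts,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$t <- NA_real_; out$df <- NA_real_; out$p <- NA_real_
  k <- 0L
  for (cc in seq_len(d[3L])) for (r in seq_len(d[2L])) {
    k <- k + 1L
    xtr <- features[tr, r, cc]; xdd <- features[dd, r, cc]
    if (var(xtr) + var(xdd) < 1e-24)
      stop("zero pooled variance for ROI ", rois[r], ", contrast ",
           contrasts[cc])
    tt <- t.test(xtr, xdd, var.equal = TRUE)
    out$t[k] <- unname(tt$statistic)
    out$df[k] <- unname(tt$parameter)
    out$p[k] <- tt$p.value
  }
  out
}

#' Pooled two-sample t from printed summary statistics
#'
#' Recomputes the Student t statistic from per-group means, SDs and sizes:
#' `t = (mean_tr - mean_dd) / (s_p sqrt(1/n1 + 1/n2))` with the pooled SD
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`. Used to verify
#' published group comparisons from their printed moments alone.
#'
#' @param mean_dd,sd_dd,n_dd moments and size of the DD group.
#' @param mean_tr,sd_tr,n_tr moments and size of the TR group.
#' @return List with `t` (TR minus DD), `df`, `p` (two-sided).
#' @examples
#' t_from_summary(10.59, 1.78, 22, 13.70, 2.82, 22)  # t ~ 4.37
#' @export
t_from_summary <- function(mean_dd, sd_dd, n_dd, mean_tr, sd_tr, n_tr) {
  stopifnot(n_dd >= 2, n_tr >= 2, sd_dd >= 0, sd_tr >= 0)
  df <- n_dd + n_tr - 2
  sp2 <- ((n_dd - 1) * sd_dd^2 + (n_tr - 1) * sd_tr^2) / df
  if (sp2 <= 0) stop("zero pooled variance")
  t <- (mean_tr - mean_dd) / (sqrt(sp2) * sqrt(1 / n_dd + 1 / n_tr))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-square test on a contingency table of counts
#'
#' Pearson's chi-square without continuity correction (the convention that
#' reproduces the published sex-by-group statistic), df =
#' (rows - 1)(cols - 1).
#'
#' @param counts matrix of counts (e.g. 2 x k groups by category).
#' @return List with `chisq`, `df`, `p`. Errors if any expected count is
#'   not positive.
#' @examples
#' chi_square_counts(rbind(c(16, 6), c(15, 7)))  # ~ 0.11
#' @export
chi_square_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal in the contingency table")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0)) stop("non-positive expected count")
  res <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(chisq = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Neuropsychological composite scores
#'
#' Reading composite: mean of the six reading z-scores (text, single word
#' and pseudo-word reading, accuracy and speed each). Verbal working
#' memory composite: mean of the four span z-scores (letters/digits,
#' forward/backward). Phonology: the nonword-repetition z-score alone.
#'
#' @param neuropsych data frame with one row per subject and the component
#'   columns named as in [table1_summary()] (`TR_accuracy`, `TR_speed`,
#'   `SWR_accuracy`, `SWR_speed`, `SPWR_accuracy`, `SPWR_speed`, `SLFS`,
#'   `SLBS`, `SDFS`, `SDBS`, `SNWR`).
#' @return Data frame with per-subject `reading`, `vwm`, `phonology` (plus
#'   `subject`/`group` columns if present in the input).
#' @export
composite_scores <- function(neuropsych) {
  reading_parts <- c("TR_accuracy", "TR_speed", "SWR_accuracy",
                     "SWR_speed", "SPWR_accuracy", "SPWR_speed")
  vwm_parts <- c("SLFS", "SLBS", "SDFS", "SDBS")
  needed <- c(reading_parts, vwm_parts, "SNWR")
  missing <- setdiff(needed, names(neuropsych))
  if (length(missing))
    stop("missing component column(s): ", paste(missing, collapse = ", "))
  out <- data.frame(
    reading = rowMeans(neuropsych[reading_parts]),
    vwm = rowMeans(neuropsych[vwm_parts]),
    phonology = neuropsych$SNWR)
  for (extra in c("subject", "group"))
    if (extra %in% names(neuropsych))
      out[[extra]] <- neuropsych[[extra]]
  out
}

#' Brain-behavior Pearson correlations with Bonferroni flags
#'
#' Pearson correlation of each (ROI in `roi_subset`, contrast) feature with
#' each neuropsychological domain over the pooled sample (both groups),
#' with two-sided p-values and a Bonferroni significance flag at
#' `alpha / (n_rois x n_contrasts x n_domains)`.
#'
#' @param features subjects x ROIs x contrasts array (residualized by
#'   default in the pipeline; pass raw features to reproduce an
#'   unadjusted analysis).
#' @param composites data frame of per-subject domain scores (columns used:
#'   `reading`, `vwm`, `phonology`, or any numeric columns present).
#' @param roi_subset ROI indices to test (e.g. the selected set).
#' @param alpha family-wise error rate (default 0.05).
#' @return Data frame per (roi, contrast, domain): `r`, `p`,
#'   `significant`; the Bonferroni threshold is attached as attribute
#'   `threshold`.
#' @export
roi_behavior_correlations <- function(features, composites, roi_subset,
                                      alpha = 0.05) {
  check_features(features)
  if (!length(roi_subset)) stop("roi_subset must be non-empty")
  domains <- names(composites)[vapply(composites, is.numeric, logical(1))]
  if (nrow(composites) != dim(features)[1L])
    stop("composites must align with the feature subjects")
  d <- dim(features)
  dn <- dimnames(features)
  rois <- if (is.null(dn[[2L]])) sprintf("roi%03d", seq_len(d[2L]))
          else dn[[2L]]
  contrasts <- if (is.null(dn[[3L]])) paste0("contrast", seq_len(d[3L]))
               else dn[[3L]]
  thr <- bonferroni_threshold(length(roi_subset), d[3L], length(domains),
                              alpha)
  rows <- list()
  k <- 0L
  for (r in roi_subset) for (cc in seq_len(d[3L])) for (dom in domains) {
    x <- features[, r, cc]
    yv <- composites[[dom]]
    ok <- !is.na(x) & !is.na(yv)  # pairwise deletion, per-cell n recorded
    if (sum(ok) < 3L) stop("fewer than 3 complete pairs for domain ", dom)
    if (sd(x[ok]) < 1e-12 || sd(yv[ok]) < 1e-12)
      stop("zero variance in ROI ", rois[r], " / domain ", dom)
    ct <- cor.test(x[ok], yv[ok], method = "pearson")
    k <- k + 1L
    rows[[k]] <- data.frame(roi = rois[r], contrast = contrasts[cc],
                            domain = dom, n = sum(ok),
                            r = unname(ct$estimate), p = ct$p.value,
                            significant = ct$p.value < thr)
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}

#' Bonferroni significance threshold for the correlation family
#'
#' `alpha / (n_rois x n_contrasts x n_domains)`; e.g. 11 ROIs x 5
#' contrasts x 3 domains at alpha 0.05 gives 0.05/165 ~ 0.0003.
#'
#' @param n_rois,n_contrasts,n_domains family size factors (each >= 1).
#' @param alpha family-wise error rate in (0, 1).
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(n_rois, n_contrasts, n_domains,
                                 alpha = 0.05) {
  stopifnot(n_rois >= 1, n_contrasts >= 1, n_domains >= 1,
            alpha > 0, alpha < 1)
  alpha / (n_rois * n_contrasts * n_domains)
}

#' Published descriptive statistics of the study sample
#'
#' The printed per-group summary (mean, SD, and where reported per-group n)
#' of the demographic and neuropsychological measures, shipped as a CSV
#' fixture, together with the published t/df for cross-checking. Rows with
#' missing per-group n (the published df of 41/40/39 implies unreported
#' missingness) carry `NA` and are skipped by [recompute_table1()].
#'
#' @return Data frame with columns `measure`, `dd_mean`, `dd_sd`, `dd_n`,
#'   `tr_mean`, `tr_sd`, `tr_n`, `published_t`, `published_df`.
#' @export
table1_summary <- function() {
  read.csv(system.file("extdata", "table1_summary.csv",
                       package = "roimkl"),
           stringsAsFactors = FALSE)
}

#' Recompute published group comparisons from printed moments
#'
#' Applies [t_from_summary()] to every row of [table1_summary()] with
#' complete per-group n, returning recomputed and published t side by
#' side.
#'
#' @param summary data frame in the [table1_summary()] format.
#' @return Data frame with `measure`, `t`, `df`, `p`, `published_t`,
#'   `delta` (recomputed minus published).
#' @export
recompute_table1 <- function(summary = table1_summary()) {
  keep <- !is.na(summary$dd_n) & !is.na(summary$tr_n)
  s <- summary[keep, , drop = FALSE]
  res <- lapply(seq_len(nrow(s)), function(i)
    t_from_summary(s$dd_mean[i], s$dd_sd[i], s$dd_n[i],
                   s$tr_mean[i], s$tr_sd[i], s$tr_n[i]))
  data.frame(measure = s$measure,
             t = vapply(res, `[[`, numeric(1), "t"),
             df = vapply(res, `[[`, numeric(1), "df"),
             p = vapply(res, `[[`, numeric(1), "p"),
             published_t = s$published_t,
             delta = vapply(res, `[[`, numeric(1), "t") - s$published_t)
}
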