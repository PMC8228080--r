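#' Mean contrast value per atlas region
#'
#' Averages a per-unit contrast map over the units carrying each integer
#' ROI label. Label 0 marks unassigned units and is ignored.
#'
#' @param map numeric per-unit contrast values.
#' @param labels integer per-unit ROI labels (0 = unassigned), same length
#'   as `map`; labels are expected to be dense in `1..n_rois`.
#' @param n_rois number of ROIs; defaults to `max(labels)`.
#' @return Named numeric vector of length `n_rois` with one mean per ROI.
#'   Errors if any ROI in `1..n_rois` has no units.
#' @export
extract_roi_means <- function(map, labels, n_rois = max(labels)) {
  stopifnot(length(map) == length(labels))
  labels <- as.integer(labels)
  if (n_rois < 1L) stop("parcellation has no ROIs")
  keep <- labels > 0L
  counts <- tabulate(labels[keep], nbins = n_rois)
  if (any(counts == 0L))
    stop("empty ROI(s): ", paste(which(counts == 0L), collapse = ", "))
  sums <- vapply(seq_len(n_rois),
                 function(r) sum(map[keep][labels[keep] == r]), numeric(1))
  setNames(sums / counts, sprintf("roi%03d", seq_len(n_rois)))
}

#' Residualize ROI features on confound covariates
#'
#' For every (ROI, contrast) cell, fits ordinary least squares of the
#' feature on an intercept plus the (centered) covariates over all supplied
#' subjects, and replaces the feature with its residual plus the grand mean,
#' so features keep an interpretable scale while becoming orthogonal to the
#' confounds. Residualization never sees group labels; by default (as in
#' the original analysis order) it is fit on the full pooled sample before
#' any classification, which [nested_mkl_cv()] can instead redo within
#' training folds via its `confounds` argument.
#'
#' Zero-variance covariates are dropped (a covariate that does not vary
#' cannot explain signal); if all are dropped the input is returned
#' unchanged apart from the `residualized` attribute.
#'
#' @param features subjects x ROIs x contrasts array.
#' @param covariates data frame or matrix of per-subject confound values
#'   (by default a performance-IQ score and an inattention score), aligned
#'   with the subject dimension.
#' @return The feature array with confound-explained signal removed;
#'   attribute `residualized` set to `TRUE`.
#' @export
residualize_confounds <- function(features, covariates) {
  check_features(features)
  Z <- as.matrix(covariates)
  if (nrow(Z) != dim(features)[1L])
    stop("covariates must have one row per subject")
  if (anyNA(Z)) stop("covariates contain missing values")
  if (nrow(Z) < ncol(Z) + 3L)
    stop("need at least 3 more subjects than covariates")
  Z <- scale(Z, center = TRUE, scale = FALSE)
  keep <- apply(Z, 2L, function(z) sd(z) > 1e-12)
  Z <- Z[, keep, drop = FALSE]
  out <- features
  if (ncol(Z) > 0L) {
    if (qr(Z)$rank < ncol(Z)) stop("collinear covariates")
    d <- dim(features)
    M <- matrix(features, nrow = d[1L])
    fit <- lm.fit(cbind(1, Z), M)
    res <- as.matrix(fit$residuals)
    grand <- colMeans(M)
    out <- array(res + rep(grand, each = d[1L]), dim = d,
                 dimnames = dimnames(features))
  }
  attr(out, "residualized") <- TRUE
  out
}
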