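#' Default hyperparameter grid for the MKL classifier
#'
#' C spans `2^{-5} .. 2^5` in factor-of-4 steps; the norm parameter p spans
#' the sparse (1.05, standing in for the group-lasso limit p = 1 while
#' keeping the weight update finite) to dense (4) regimes.
#'
#' @return Data frame with columns `C` and `p`, ordered by C then p (the
#'   tie-breaking order of the grid search).
#' @export
default_mkl_grid <- function() {
  g <- expand.grid(p = c(1.05, 4 / 3, 2, 4),
                   C = 2^c(-5, -3, -1, 1, 3, 5))
  g <- g[order(g$C, g$p), c("C", "p")]
  rownames(g) <- NULL
  g
}

# Remove the covariate-explained part of every feature column, with
# coefficients estimated on the training subjects only, applied to all rows.
residualize_rows <- function(X, Z, train) {
  Z <- as.matrix(Z)
  Zc <- sweep(Z, 2L, colMeans(Z[train, , drop = FALSE]))
  keep <- apply(Zc[train, , drop = FALSE], 2L, function(z) sd(z) > 1e-12)
  Zc <- Zc[, keep, drop = FALSE]
  if (ncol(Zc) == 0L) return(X)
  fit <- lm.fit(cbind(1, Zc[train, , drop = FALSE]),
                X[train, , drop = FALSE])
  co <- as.matrix(fit$coefficients)[-1L, , drop = FALSE]
  X - Zc %*% co
}

#' Leave-one-pair-out cross-validation at fixed hyperparameters
#'
#' The outer validation loop of the classifier: each fold holds out one DD
#' and one TR subject (so 22 folds for the 22+22 study design), pairs being
#' formed by a seeded random permutation within each group.
#' Standardization and kernels are rebuilt from the training subjects of
#' every fold; if `confounds` is supplied, confound residualization is also
#' re-fit on each fold's training subjects (avoiding train/test leakage).
#'
#' @param features subjects x ROIs x contrasts array (or matrix with
#'   `n_rois`).
#' @param labels +1 (DD) / -1 (TR); groups must be equal sized.
#' @param C,p MKL hyperparameters.
#' @param seed seed for the pairing permutation.
#' @param confounds optional per-subject covariate table for fold-wise
#'   residualization.
#' @param fold_id optional explicit fold assignment (overrides pairing).
#' @param n_rois required if `features` is a matrix.
#' @param tol,max_alt passed to the MKL optimizer.
#' @return Object of class `"mkl_cv"`: per-subject `decision` and
#'   `prediction`, per-fold `beta` (folds x ROIs), `accuracy`, `auc`,
#'   `fold_id`, and the hyperparameters used.
#' @export
mkl_cv <- function(features, labels, C = 1, p = 1.05, seed = 1L,
                   confounds = NULL, fold_id = NULL, n_rois = NULL,
                   tol = 1e-4, max_alt = 200L) {
  X <- flatten_features(features)
  if (is.null(n_rois)) n_rois <- dim(features)[2L]
  y <- check_labels(labels, nrow(X))
  if (is.null(fold_id))
    fold_id <- pair_folds(y, substream_seed(seed, "pairs"))
  k <- max(fold_id)
  if (is.null(confounds)) {
    res <- cpp_cv(X, y, as.integer(fold_id), n_rois, C, p, tol = tol,
                  max_alt = max_alt)
    dec <- res$decision; pred <- res$prediction; betas <- res$beta
  } else {
    dec <- numeric(length(y)); pred <- numeric(length(y))
    betas <- matrix(0, k, n_rois)
    for (f in seq_len(k)) {
      test <- which(fold_id == f)
      train <- which(fold_id != f)
      Xf <- residualize_rows(X, confounds, train)
      r <- cpp_fit_predict(Xf, y, train - 1L, test - 1L, n_rois, C, p,
                           tol = tol, max_alt = max_alt)
      dec[test] <- r$decision
      pred[test] <- r$prediction
      betas[f, ] <- r$beta
    }
  }
  ev <- evaluate_classifier(pred, dec, y)
  structure(list(decision = dec, prediction = pred, beta = betas,
                 accuracy = ev$accuracy, auc = ev$auc, fold_id = fold_id,
                 C = C, p = p, seed = seed, labels = y),
            class = "mkl_cv")
}

#' @export
print.mkl_cv <- function(x, ...) {
  cat("Leave-one-pair-out CV:", max(x$fold_id), "folds\n")
  cat("  C =", x$C, " p =", x$p, "\n")
  cat("  accuracy =", format(x$accuracy, digits = 3),
      "  AUC =", format(x$auc, digits = 3), "\n")
  invisible(x)
}

#' Nested (double) cross-validation with grid search
#'
#' The outer loop is leave-one-pair-out (one DD and one TR per fold); for
#' each outer training set a stratified 10-fold inner loop scans the (C, p)
#' grid and the winning cell (ties broken toward smaller C, then smaller p)
#' is refit on the full outer training set to predict the held-out pair.
#' Standardization and kernels are always rebuilt inside each outer
#' training set; with `confounds`, residualization is too. Aggregate
#' accuracy and AUC are computed from the pooled held-out predictions and
#' decision values.
#'
#' @inheritParams mkl_cv
#' @param grid data frame of candidate `C`, `p` (default
#'   [default_mkl_grid()]).
#' @param inner_folds number of inner folds (default 10).
#' @return Object of class `"mkl_nested_cv"` (also `"mkl_cv"`): as
#'   [mkl_cv()] plus `fold_hp`, the per-fold winning hyperparameters.
#' @export
nested_mkl_cv <- function(features, labels, grid = default_mkl_grid(),
                          seed = 1L, inner_folds = 10L, confounds = NULL,
                          n_rois = NULL, tol = 1e-4, max_alt = 200L) {
  X <- flatten_features(features)
  if (is.null(n_rois)) n_rois <- dim(features)[2L]
  y <- check_labels(labels, nrow(X))
  if (nrow(grid) < 1L) stop("empty hyperparameter grid")
  grid <- grid[order(grid$C, grid$p), , drop = FALSE]
  fold_id <- pair_folds(y, substream_seed(seed, "pairs"))
  k <- max(fold_id)
  dec <- numeric(length(y)); pred <- numeric(length(y))
  betas <- matrix(0, k, n_rois)
  fold_hp <- data.frame(fold = seq_len(k), C = NA_real_, p = NA_real_)
  for (f in seq_len(k)) {
    test <- which(fold_id == f)
    train <- which(fold_id != f)
    Xf <- if (is.null(confounds)) X
          else residualize_rows(X, confounds, train)
    inner_id <- stratified_folds(y[train], inner_folds,
                                 substream_seed(seed, paste0("inner-", f)))
    acc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      acc[g] <- tryCatch(
        cpp_cv(Xf[train, , drop = FALSE], y[train],
               as.integer(inner_id), n_rois, grid$C[g], grid$p[g],
               tol = tol, max_alt = max_alt)$accuracy,
        error = function(e) {
          warning("grid cell (C=", grid$C[g], ", p=", grid$p[g],
                  ") failed in fold ", f, ": ", conditionMessage(e))
          -Inf
        })
    }
    best <- which.max(acc)  # grid pre-ordered: ties go to smaller C then p
    fold_hp$C[f] <- grid$C[best]
    fold_hp$p[f] <- grid$p[best]
    r <- cpp_fit_predict(Xf, y, train - 1L, test - 1L, n_rois,
                         grid$C[best], grid$p[best], tol = tol,
                         max_alt = max_alt)
    dec[test] <- r$decision
    pred[test] <- r$prediction
    betas[f, ] <- r$beta
  }
  ev <- evaluate_classifier(pred, dec, y)
  structure(list(decision = dec, prediction = pred, beta = betas,
                 accuracy = ev$accuracy, auc = ev$auc, fold_id = fold_id,
                 fold_hp = fold_hp, grid = grid, seed = seed, labels = y),
            class = c("mkl_nested_cv", "mkl_cv"))
}

#' @export
print.mkl_nested_cv <- function(x, ...) {
  cat("Nested (double) CV:", max(x$fold_id),
      "outer leave-one-pair-out folds\n")
  cat("  accuracy =", format(x$accuracy, digits = 3),
      "  AUC =", format(x$auc, digits = 3), "\n")
  hp <- consensus_hyperparams(x)
  cat("  consensus hyperparameters: C =", hp$C, " p =", hp$p, "\n")
  invisible(x)
}

#' Consensus hyperparameters across outer folds
#'
#' The per-parameter mode of the fold-winning values, ties broken toward
#' smaller C, then smaller p. This is the configuration the backward
#' elimination consumes.
#'
#' @param cv an `"mkl_nested_cv"` result.
#' @return List with `C` and `p`.
#' @export
consensus_hyperparams <- function(cv) {
  hp <- if (inherits(cv, "mkl_nested_cv")) cv$fold_hp
        else stop("consensus requires a nested CV result")
  mode_min <- function(v) {
    vals <- sort(unique(v))
    counts <- vapply(vals, function(x) sum(v == x), integer(1))
    vals[which.max(counts)]  # first max: ties go to the smaller value
  }
  list(C = mode_min(hp$C), p = mode_min(hp$p))
}

#' Fold-averaged, max-rescaled ROI weights
#'
#' Mean kernel weight per ROI across the outer folds, divided by its
#' maximum so the top ROI scores 1 (the presentation used for the ROI
#' ranking), returned in decreasing order.
#'
#' @param cv an `"mkl_cv"` or `"mkl_nested_cv"` result.
#' @param roi_names optional ROI names.
#' @return Named numeric vector in `[0, 1]`, max = 1, sorted decreasing.
#' @export
roi_weight_summary <- function(cv, roi_names = NULL) {
  stopifnot(inherits(cv, "mkl_cv"))
  w <- colMeans(cv$beta)
  if (max(w) <= 0) stop("all fold-mean ROI weights are zero")
  if (is.null(roi_names)) roi_names <- sprintf("roi%03d", seq_along(w))
  sort(setNames(w / max(w), roi_names), decreasing = TRUE)
}

#' Permutation test of classifier performance
#'
#' Recomputes the cross-validated accuracy under uniformly shuffled subject
#' labels. Mode `"fixed"` (the tractable default) re-runs the outer
#' leave-one-pair-out CV at fixed hyperparameters per permutation; mode
#' `"full"` re-runs the entire nested grid search per permutation. Outer
#' folds are re-formed for each permutation so every fold keeps one subject
#' of each (permuted) label. The p-value uses the add-one estimator
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`, which is never zero.
#'
#' @inheritParams mkl_cv
#' @param n_perm number of label permutations (>= 1; the study protocol
#'   used 10000).
#' @param mode `"fixed"` or `"full"`.
#' @param grid grid for `"full"` mode.
#' @param observed optionally, a precomputed observed `"mkl_cv"` result to
#'   reuse (must match the configuration).
#' @return Object of class `"mkl_perm"`: `observed` (accuracy), `null`
#'   (vector of permuted accuracies), `p_value`, `n_perm`, `mode`,
#'   `observed_cv`.
#' @export
mkl_permutation_test <- function(features, labels, n_perm = 10000L,
                                 seed = 1L, mode = c("fixed", "full"),
                                 C = 1, p = 1.05,
                                 grid = default_mkl_grid(),
                                 confounds = NULL, n_rois = NULL,
                                 observed = NULL, tol = 1e-4,
                                 max_alt = 200L) {
  mode <- match.arg(mode)
  if (n_perm < 1L) stop("n_perm must be at least 1")
  y <- check_labels(labels, if (is.matrix(features)) nrow(features)
                            else dim(features)[1L])
  run1 <- function(lab, sd) {
    if (mode == "fixed")
      mkl_cv(features, lab, C = C, p = p, seed = sd,
             confounds = confounds, n_rois = n_rois, tol = tol,
             max_alt = max_alt)
    else
      nested_mkl_cv(features, lab, grid = grid, seed = sd,
                    confounds = confounds, n_rois = n_rois, tol = tol,
                    max_alt = max_alt)
  }
  if (is.null(observed))
    observed <- run1(y, substream_seed(seed, "observed"))
  null_acc <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(substream_seed(seed, paste0("perm-", b)))
    yb <- sample(y)
    null_acc[b] <- run1(yb, substream_seed(seed, paste0("perm-cv-", b)))$accuracy
  }
  pv <- (1 + sum(null_acc >= observed$accuracy)) / (1 + n_perm)
  structure(list(observed = observed$accuracy, null = null_acc,
                 p_value = pv, n_perm = n_perm, mode = mode, seed = seed,
                 observed_cv = observed),
            class = "mkl_perm")
}

#' @export
print.mkl_perm <- function(x, ...) {
  cat("Permutation test (", x$mode, " mode, ", x$n_perm,
      " permutations)\n", sep = "")
  cat("  observed accuracy =", format(x$observed, digits = 3),
      "  p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
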