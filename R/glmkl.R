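#' Per-ROI linear kernels from a contrast feature table
#'
#' For each ROI, the five contrast means are concatenated into one input
#' vector (preserving the topological information among the tasks), each
#' feature is z-scored using the training subjects' moments, and a linear
#' Gram matrix is formed and trace-normalized to `trace = n_train`. Test
#' rows must be standardized with the training moments, which
#' [cross_roi_kernels()] does.
#'
#' @param features subjects x ROIs x contrasts array (or pre-flattened
#'   subjects x (ROIs*contrasts) matrix with `n_rois` supplied).
#' @param train_ids subject indices to build the kernels on (default all).
#' @param n_rois number of ROIs if `features` is a matrix.
#' @return Object of class `"roi_kernels"`: list with `kernels` (list of
#'   symmetric PSD matrices, one per ROI), `center`/`scale` (per-feature
#'   training moments; zero-variance features are dropped with a warning),
#'   `trace_scale`, `train_ids`, `n_rois`, `n_contrasts`.
#' @export
build_roi_kernels <- function(features, train_ids = NULL, n_rois = NULL) {
  X <- flatten_features(features)
  if (is.null(n_rois)) {
    stopifnot(length(dim(features)) == 3L)
    n_rois <- dim(features)[2L]
  }
  nc <- ncol(X) / n_rois
  stopifnot(nc == round(nc))
  if (is.null(train_ids)) train_ids <- seq_len(nrow(X))
  Xtr <- X[train_ids, , drop = FALSE]
  center <- colMeans(Xtr)
  scale <- apply(Xtr, 2L, sd)
  dead <- scale < 1e-12
  if (any(dead)) {
    warning(sum(dead), " zero-variance feature(s) in the training set ",
            "dropped")
    scale[dead] <- 1
  }
  Xs <- sweep(sweep(Xtr, 2L, center), 2L, scale, "/")
  Xs[, dead] <- 0
  kernels <- vector("list", n_rois)
  trace_scale <- numeric(n_rois)
  ntr <- length(train_ids)
  for (m in seq_len(n_rois)) {
    cols <- ((m - 1L) * nc + 1L):(m * nc)
    K <- tcrossprod(Xs[, cols, drop = FALSE])
    tr <- sum(diag(K))
    s <- if (tr > 1e-12) ntr / tr else 1
    kernels[[m]] <- K * s
    trace_scale[m] <- s
  }
  structure(list(kernels = kernels, center = center, scale = scale,
                 dead = dead, trace_scale = trace_scale,
                 train_ids = train_ids, n_rois = n_rois, n_contrasts = nc,
                 X_std = Xs),
            class = "roi_kernels")
}

#' @describeIn build_roi_kernels Cross kernels between new subjects and the
#'   training subjects, using training standardization and trace scaling.
#' @param kset a `"roi_kernels"` object.
#' @param newdata feature array/matrix in the same feature space.
#' @export
cross_roi_kernels <- function(kset, newdata) {
  Xn <- flatten_features(newdata)
  if (ncol(Xn) != length(kset$center))
    stop("newdata feature space does not match the kernel set")
  Xs <- sweep(sweep(Xn, 2L, kset$center), 2L, kset$scale, "/")
  Xs[, kset$dead] <- 0
  nc <- kset$n_contrasts
  lapply(seq_len(kset$n_rois), function(m) {
    cols <- ((m - 1L) * nc + 1L):(m * nc)
    tcrossprod(Xs[, cols, drop = FALSE],
               kset$X_std[, cols, drop = FALSE]) * kset$trace_scale[m]
  })
}

#' Fit a group-lasso (lp-norm) multiple kernel learning SVM
#'
#' The core classifier: one linear kernel per ROI, combined with learned
#' nonnegative weights `beta` constrained to the lp-norm unit ball
#' (`||beta||_p = 1`). Small `p` (near 1) drives the weight profile sparse
#' (the group-lasso regime); large `p` approaches uniform weighting. The
#' fit alternates (i) solving the C-SVM dual on the combined kernel
#' `K(beta) = sum_m beta_m K_m` and (ii) the closed-form update
#' `beta_m ~ ||w_m||^(2/(p+1))` renormalized to the lp ball, where
#' `||w_m||^2 = beta_m^2 (alpha y)' K_m (alpha y)`, until
#' `max |d beta| < tol` or `max_alt` alternations (non-convergence returns
#' the best iterate with a warning). The decision function is
#' `f(x) = sum_i alpha_i y_i sum_m beta_m K_m(x_i, x) + b`; DD is the +1
#' target class and ties (`f = 0`) go to TR (-1).
#'
#' @param x subjects x ROIs x contrasts feature array (or flattened matrix
#'   with `n_rois`).
#' @param y labels, +1 (DD) / -1 (TR).
#' @param C SVM error penalty (> 0).
#' @param p sparsity/norm parameter (>= 1; values very close to 1 are
#'   numerically delicate, 1.05 is the sparse default).
#' @param n_rois required if `x` is a matrix.
#' @param tol convergence tolerance on `max |d beta|`.
#' @param max_alt maximum alternations.
#' @return Object of class `"glmkl"` with elements `beta` (per-ROI kernel
#'   weights), `alpha` (dual coefficients), `b` (bias), `y`, `C`, `p`,
#'   `kernels` (the `"roi_kernels"` set, holding the training
#'   standardization), `objective_trace`, `converged`.
#' @examples
#' coh <- simulate_cohort(n_per_group = 8, n_rois = 6,
#'                        informative_rois = 1, effect_sizes = 2, seed = 2)
#' fit <- glmkl(coh$features, coh$labels, C = 1, p = 1.05)
#' coef(fit)
#' @export
glmkl <- function(x, y, C = 1, p = 1.05, n_rois = NULL, tol = 1e-4,
                  max_alt = 200L) {
  if (C <= 0) stop("C must be positive")
  if (p < 1) stop("p must be at least 1")
  kset <- build_roi_kernels(x, n_rois = n_rois)
  y <- check_labels(y, nrow(kset$X_std))
  n <- length(y)
  R <- kset$n_rois
  cube <- array(unlist(kset$kernels), dim = c(n, n, R))
  fit <- cpp_mkl_train(cube, y, C, p, tol = tol, max_alt = max_alt)
  if (!fit$converged)
    warning("MKL alternation did not converge in ", max_alt,
            " iterations; returning last iterate")
  roi_names <- if (is.array(x) && length(dim(x)) == 3L &&
                   !is.null(dimnames(x)[[2L]])) dimnames(x)[[2L]]
               else sprintf("roi%03d", seq_len(R))
  structure(list(beta = setNames(as.numeric(fit$beta), roi_names),
                 alpha = as.numeric(fit$alpha), b = fit$b, y = y,
                 C = C, p = p, kernels = kset,
                 support = which(fit$alpha > 1e-8),
                 objective_trace = as.numeric(fit$objective_trace),
                 converged = fit$converged, call = match.call()),
            class = "glmkl")
}

#' @export
print.glmkl <- function(x, ...) {
  cat("lp-norm multiple kernel learning SVM\n")
  cat("  C =", x$C, " p =", x$p, " ROIs =", length(x$beta),
      " subjects =", length(x$y), "\n")
  cat("  support vectors:", length(x$support),
      " converged:", x$converged, "\n")
  top <- sort(x$beta, decreasing = TRUE)
  top <- top[top > 0]
  cat("  top kernel weights:\n")
  print(head(round(top, 4), 5))
  invisible(x)
}

#' @export
coef.glmkl <- function(object, ...) object$beta

#' @export
summary.glmkl <- function(object, ...) {
  dec <- predict(object, type = "decision")
  acc <- mean(ifelse(dec > 0, 1, -1) == object$y)
  out <- list(C = object$C, p = object$p, beta = object$beta,
              n_support = length(object$support),
              training_accuracy = acc,
              lp_norm = sum(object$beta^object$p)^(1 / object$p),
              converged = object$converged)
  class(out) <- "summary.glmkl"
  out
}

#' @export
print.summary.glmkl <- function(x, ...) {
  cat("lp-norm MKL SVM: C =", x$C, " p =", x$p, "\n")
  cat("  ||beta||_p =", format(x$lp_norm, digits = 6),
      "  nonzero weights:", sum(x$beta > 1e-8), "/", length(x$beta), "\n")
  cat("  support vectors:", x$n_support,
      "  training accuracy:", format(x$training_accuracy, digits = 3),
      "\n")
  invisible(x)
}

#' Predict group membership from a fitted MKL model
#'
#' @param object a `"glmkl"` fit.
#' @param newdata feature array/matrix in the training feature space;
#'   omitted for training-set predictions.
#' @param type `"class"` for +1/-1 labels (ties assigned to TR, -1) or
#'   `"decision"` for raw decision values.
#' @param ... unused.
#' @return Numeric vector of labels or decision values.
#' @export
predict.glmkl <- function(object, newdata = NULL,
                          type = c("class", "decision"), ...) {
  type <- match.arg(type)
  Kx <- if (is.null(newdata)) {
    lapply(seq_along(object$kernels$kernels),
           function(m) object$kernels$kernels[[m]])
  } else cross_roi_kernels(object$kernels, newdata)
  ay <- object$alpha * object$y
  f <- rep(object$b, nrow(Kx[[1L]]))
  for (m in seq_along(Kx))
    if (object$beta[m] > 0) f <- f + object$beta[m] * (Kx[[m]] %*% ay)
  f <- as.numeric(f)
  if (type == "decision") f else ifelse(f > 0, 1, -1)
}

#' Classification accuracy and AUC
#'
#' Accuracy is the fraction of correct labels; AUC is the Mann-Whitney
#' statistic of the decision values (probability that a random DD subject
#' scores above a random TR subject, ties counted 1/2).
#'
#' @param predictions predicted labels (+1/-1).
#' @param decision_values raw decision values.
#' @param labels true labels (+1/-1); both classes must be present.
#' @return List with `accuracy` and `auc`.
#' @export
evaluate_classifier <- function(predictions, decision_values, labels) {
  stopifnot(length(predictions) == length(labels),
            length(decision_values) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("AUC undefined: one class absent")
  pos <- labels == 1
  r <- rank(decision_values)
  auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))
  list(accuracy = mean(predictions == labels), auc = auc)
}
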