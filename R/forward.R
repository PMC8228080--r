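#' Transform backward MKL weights into forward activation patterns
#'
#' Discriminative (backward) model weights are not directly interpretable
#' as activation: a feature can receive a large weight merely to cancel
#' noise shared with other features. The forward transformation maps the
#' model's primal weight vector `w` onto activation-pattern weights
#' `a = Cov(X) w / Var(s)`, where `X` is the standardized feature matrix
#' over the chosen subjects and `s = X w` is the decision score (up to the
#' bias). Each entry of `a` is then interpretable as the association of
#' that (ROI, contrast) feature with the classifier score, the target class
#' being DD (+1) — so with higher TR activation in discriminative ROIs the
#' forward weights come out negative.
#'
#' The primal block for ROI m in the trace-scaled standardized feature
#' space is `w_m = beta_m s_m X_m' (alpha * y)` with `s_m` the kernel trace
#' scale. Covariance uses denominator n - 1. No rescaling is applied to
#' the forward weights.
#'
#' @param model a fitted [glmkl()] model (typically trained on all
#'   subjects, with the consensus hyperparameters, on the selected ROI
#'   set).
#' @param subjects subject indices over which to compute the data
#'   covariance (default: the model's training subjects).
#' @return Object of class `"forward_weights"`: a ROIs x contrasts matrix
#'   of activation weights, with attributes `w` (the primal weight vector)
#'   and `var_score`.
#' @export
forward_weights <- function(model, subjects = NULL) {
  stopifnot(inherits(model, "glmkl"))
  kset <- model$kernels
  Xs <- kset$X_std
  if (!is.null(subjects)) Xs <- Xs[subjects, , drop = FALSE]
  if (nrow(Xs) < 3L) stop("need at least 3 subjects")
  nc <- kset$n_contrasts
  ay <- model$alpha * model$y
  w <- numeric(ncol(Xs))
  for (m in seq_len(kset$n_rois)) {
    cols <- ((m - 1L) * nc + 1L):(m * nc)
    w[cols] <- model$beta[m] * kset$trace_scale[m] *
      crossprod(kset$X_std[, cols, drop = FALSE], ay)
  }
  s <- as.numeric(Xs %*% w)
  vs <- var(s)
  if (vs < 1e-12) stop("degenerate score: Var(s) = 0")
  Sigma <- cov(Xs)
  a <- as.numeric(Sigma %*% w) / vs
  out <- matrix(a, nrow = kset$n_rois, ncol = nc, byrow = TRUE,
                dimnames = list(names(model$beta),
                                if (nc == 5L) CONTRAST_NAMES
                                else paste0("contrast", seq_len(nc))))
  attr(out, "w") <- w
  attr(out, "var_score") <- vs
  class(out) <- c("forward_weights", class(out))
  out
}

#' @export
print.forward_weights <- function(x, ...) {
  cat("Forward (activation pattern) weights:", nrow(x), "ROIs x",
      ncol(x), "contrasts\n")
  print(round(unclass(x), 3))
  invisible(x)
}
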