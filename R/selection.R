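#' Greedy backward ROI elimination under fixed hyperparameters
#'
#' Starting from all ROIs, repeatedly: run the outer leave-one-pair-out CV
#' with hyperparameters fixed to the consensus values, record accuracy,
#' AUC and the fold-mean kernel weight of every remaining ROI, then remove
#' the ROI with the smallest fold-mean weight (ties: the lowest ROI index)
#' and retrain. Each step removes exactly one ROI; the trace ends when the
#' remaining set would shrink below `floor`. CV pairings are re-randomized
#' per step from the seed substream, so the trace is reproducible but not
#' tied to one fold split.
#'
#' @inheritParams mkl_cv
#' @param floor smallest remaining-set size to retain (default 1). The last
#'   scored configuration has `floor + 1` ROIs; the final set of size
#'   `floor` is reached but not re-scored, since every step scores then
#'   removes.
#' @return Object of class `"mkl_elim"`: list with `steps` (data frame
#'   `step`, `n_rois`, `accuracy`, `auc`, `removed_roi`), `roi_sets` (the
#'   remaining ROI index set at each step, before that step's removal),
#'   `beta_means` (fold-mean weights per step), `C`, `p`, `seed`.
#' @export
backward_eliminate <- function(features, labels, C = 1, p = 1.05,
                               seed = 1L, floor = 1L, confounds = NULL,
                               n_rois = NULL, tol = 1e-4, max_alt = 200L) {
  X <- flatten_features(features)
  if (is.null(n_rois)) n_rois <- dim(features)[2L]
  nc <- ncol(X) / n_rois
  y <- check_labels(labels, nrow(X))
  if (floor < 1L || floor > n_rois)
    stop("floor must lie in 1..n_rois")
  remaining <- seq_len(n_rois)
  steps <- list()
  roi_sets <- list()
  beta_means <- list()
  s <- 0L
  while (length(remaining) > floor) {
    s <- s + 1L
    cols <- as.vector(vapply(remaining,
                             function(m) ((m - 1L) * nc + 1L):(m * nc),
                             integer(nc)))
    cv <- mkl_cv(X[, cols, drop = FALSE], y, C = C, p = p,
                 seed = substream_seed(seed, paste0("elim-", s)),
                 confounds = confounds, n_rois = length(remaining),
                 tol = tol, max_alt = max_alt)
    bm <- colMeans(cv$beta)
    drop_pos <- which.min(bm)  # first minimum: lowest ROI index on ties
    steps[[s]] <- data.frame(step = s, n_rois = length(remaining),
                             accuracy = cv$accuracy, auc = cv$auc,
                             removed_roi = remaining[drop_pos])
    roi_sets[[s]] <- remaining
    beta_means[[s]] <- setNames(bm, remaining)
    remaining <- remaining[-drop_pos]
  }
  structure(list(steps = do.call(rbind, steps), roi_sets = roi_sets,
                 beta_means = beta_means, final_set = remaining,
                 C = C, p = p, seed = seed),
            class = "mkl_elim")
}

#' @export
print.mkl_elim <- function(x, ...) {
  cat("Backward elimination:", nrow(x$steps), "steps (",
      x$steps$n_rois[1L], "down to", x$steps$n_rois[nrow(x$steps)],
      "ROIs scored )\n")
  best <- select_best(x)
  cat("  best configuration:", length(best$roi_ids), "ROIs, accuracy =",
      format(best$accuracy, digits = 3), " AUC =",
      format(best$auc, digits = 3), "\n")
  invisible(x)
}

#' Plot an elimination trace
#'
#' Classification performance against the number of remaining ROIs, the
#' standard presentation of a backward elimination run.
#'
#' @param x an `"mkl_elim"` object.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.mkl_elim <- function(x, ...) {
  st <- x$steps
  graphics::plot(st$n_rois, st$accuracy, type = "b", pch = 16,
                 xlim = rev(range(st$n_rois)),
                 xlab = "ROIs remaining", ylab = "accuracy", ...)
  graphics::lines(st$n_rois, st$auc, type = "b", pch = 1, lty = 2)
  best <- select_best(x)
  graphics::abline(v = length(best$roi_ids), col = 2, lty = 3)
  graphics::legend("bottomleft", legend = c("accuracy", "AUC"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Select the best-performing ROI subset from an elimination trace
#'
#' Argmax over steps by accuracy, ties broken by AUC, then by fewer ROIs.
#'
#' @param trace an `"mkl_elim"` object.
#' @return List with `roi_ids` (the remaining set at the winning step),
#'   `accuracy`, `auc`, `step`.
#' @export
select_best <- function(trace) {
  stopifnot(inherits(trace, "mkl_elim"))
  st <- trace$steps
  ord <- order(-st$accuracy, -st$auc, st$n_rois)
  w <- ord[1L]
  list(roi_ids = trace$roi_sets[[w]], accuracy = st$accuracy[w],
       auc = st$auc[w], step = st$step[w])
}
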