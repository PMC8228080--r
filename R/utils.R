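#' Derive a reproducible substream seed from a master seed
#'
#' All stochastic stages draw their seed from one master seed plus a stream
#' name, so that stages are individually reproducible and mutually
#' decoupled: changing the number of draws in one stage does not shift the
#' randomness of another.
#'
#' @param master integer master seed.
#' @param name character stream name (e.g. `"pairs"`, `"perm-12"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(master)) %% 2147483647 + h) %% 2147483647)
}

# Flatten a subjects x ROIs x contrasts array into the subjects x
# (ROIs*contrasts) matrix the kernel code expects: columns grouped by ROI,
# contrasts fastest within each block.
flatten_features <- function(features) {
  if (is.matrix(features)) return(features)
  stopifnot(length(dim(features)) == 3L)
  d <- dim(features)
  m <- matrix(aperm(features, c(1L, 3L, 2L)), nrow = d[1L],
              ncol = d[2L] * d[3L])
  cn <- dimnames(features)[[3L]]
  rn <- dimnames(features)[[2L]]
  if (!is.null(cn) && !is.null(rn))
    colnames(m) <- as.vector(t(outer(rn, cn, paste, sep = ".")))
  rownames(m) <- dimnames(features)[[1L]]
  m
}

# Validate a subjects x ROIs x contrasts feature array.
check_features <- function(features) {
  stopifnot(is.array(features), length(dim(features)) == 3L)
  if (anyNA(features) || any(!is.finite(features)))
    stop("feature array contains missing or non-finite values")
  invisible(features)
}

check_labels <- function(labels, n) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == n, all(labels %in% c(-1, 1)))
  if (length(unique(labels)) < 2L)
    stop("both groups (+1 = DD, -1 = TR) must be present")
  labels
}

# Leave-one-pair-out fold assignment: pair the k-th DD with the k-th TR
# after a seeded random permutation within each group.
pair_folds <- function(labels, seed) {
  dd <- which(labels == 1)
  tr <- which(labels == -1)
  if (length(dd) != length(tr))
    stop("leave-one-pair-out folds require equal group sizes (",
         length(dd), " DD vs ", length(tr), " TR)")
  set.seed(seed)
  dd <- sample(dd)
  tr <- sample(tr)
  fold <- integer(length(labels))
  fold[dd] <- seq_along(dd)
  fold[tr] <- seq_along(tr)
  fold
}

# Stratified k-fold assignment over a label vector.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
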