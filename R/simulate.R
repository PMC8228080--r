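#' Simulate a two-group ROI feature cohort
#'
#' Generates a subjects x ROIs x contrasts feature array emulating per-ROI
#' mean contrast values for two groups of children (DD coded +1, TR coded
#' -1), with group effects planted in a chosen ROI subset, confound
#' covariates whose means differ between groups and which load on the
#' features, and i.i.d. Gaussian residual noise. The planted truth is
#' returned with the cohort so downstream recovery tests consume only
#' generator output.
#'
#' The feature model is
#' `value = ROI baseline + group effect + covariate loading + subject factor
#' + noise`, where the group effect for an informative ROI r and contrast c
#' is `effect_sizes[r, c] * noise_sd` expressed as the TR-minus-DD mean
#' difference (a standardized mean difference, Cohen's d, once divided by
#' `noise_sd`).
#'
#' @param n_per_group subjects per group (default 22, the study size).
#' @param n_rois number of ROIs (default 360: 180 per hemisphere).
#' @param n_contrasts number of contrast maps (default 5).
#' @param informative_rois integer ROI indices carrying group effects
#'   (default none: a null cohort).
#' @param effect_sizes Cohen's d (TR minus DD) per informative ROI and
#'   contrast: a scalar (recycled), a vector of length
#'   `length(informative_rois)` (recycled across contrasts), or a
#'   `length(informative_rois) x n_contrasts` matrix.
#' @param confound_effects list describing the confounds. Each element is a
#'   list with `mean_dd`, `mean_tr`, `sd` (covariate distribution per group)
#'   and `loading` (feature shift in units of `noise_sd` per covariate SD).
#'   The default mimics a performance-IQ-like score (higher in TR) and an
#'   inattention-like score (higher in DD).
#' @param noise_sd residual standard deviation (> 0).
#' @param subject_factor_sd SD of an optional shared subject factor inducing
#'   within-subject correlation across contrasts (default 0: independent).
#' @param seed integer RNG seed; identical configuration and seed give
#'   bit-identical output.
#' @return An object of class `"mkl_cohort"`: a list with `features`
#'   (subjects x ROIs x contrasts array), `labels` (+1 DD / -1 TR),
#'   `covariates` (data frame), and `truth` (informative ROI set, effect
#'   size matrix, configuration).
#' @examples
#' coh <- simulate_cohort(n_per_group = 10, n_rois = 20,
#'                        informative_rois = c(3, 7), effect_sizes = 1.5,
#'                        seed = 1)
#' dim(coh$features)
#' @export
simulate_cohort <- function(n_per_group = 22L, n_rois = 360L,
                            n_contrasts = 5L, informative_rois = integer(),
                            effect_sizes = numeric(),
                            confound_effects = default_confounds(),
                            noise_sd = 1, subject_factor_sd = 0,
                            seed = 1L) {
  if (n_per_group < 2L) stop("n_per_group must be at least 2")
  if (n_rois < 1L || n_contrasts < 1L) stop("invalid cohort dimensions")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  informative_rois <- as.integer(informative_rois)
  if (length(informative_rois) &&
      (any(informative_rois < 1L) || any(informative_rois > n_rois)))
    stop("informative_rois must lie in 1..n_rois")
  if (anyDuplicated(informative_rois))
    stop("informative_rois must be distinct")
  d <- matrix(0, length(informative_rois), n_contrasts)
  if (length(informative_rois)) {
    if (is.matrix(effect_sizes)) {
      if (!all(dim(effect_sizes) == dim(d)))
        stop("effect_sizes matrix must be length(informative_rois) x n_contrasts")
      d[] <- effect_sizes
    } else {
      if (length(effect_sizes) == 0L)
        stop("effect_sizes required when informative_rois is non-empty")
      d[] <- rep_len(effect_sizes, length(informative_rois))
    }
  }

  n <- 2L * n_per_group
  labels <- rep(c(1, -1), each = n_per_group)  # DD then TR
  set.seed(seed)
  baseline <- rnorm(n_rois)
  # covariates: group-shifted means, then standardized loading on features
  covariates <- data.frame(row.names = seq_len(n))
  total_load <- rep(0, n)
  for (nm in names(confound_effects)) {
    ce <- confound_effects[[nm]]
    mu <- ifelse(labels == 1, ce$mean_dd, ce$mean_tr)
    z <- rnorm(n, mean = mu, sd = ce$sd)
    covariates[[nm]] <- z
    total_load <- total_load + ce$loading * (z - mean(c(ce$mean_dd,
                                                        ce$mean_tr))) / ce$sd
  }
  subj <- if (subject_factor_sd > 0) rnorm(n, sd = subject_factor_sd)
          else rep(0, n)

  features <- array(rnorm(n * n_rois * n_contrasts, sd = noise_sd),
                    dim = c(n, n_rois, n_contrasts))
  features <- features + rep(baseline, each = n)  # ROI baseline
  features <- features + (total_load * noise_sd + subj)  # recycled over cells
  if (length(informative_rois)) {
    half <- 0.5 * labels  # +1 DD gets -d/2, -1 TR gets +d/2: TR - DD = d
    for (k in seq_along(informative_rois)) {
      r <- informative_rois[k]
      for (cc in seq_len(n_contrasts))
        features[, r, cc] <- features[, r, cc] -
          half * d[k, cc] * noise_sd
    }
  }
  cn <- if (n_contrasts == 5L) CONTRAST_NAMES
        else paste0("contrast", seq_len(n_contrasts))
  dimnames(features) <- list(sprintf("sub-%03d", seq_len(n)),
                             sprintf("roi%03d", seq_len(n_rois)), cn)
  structure(list(
    features = features, labels = labels, covariates = covariates,
    truth = list(informative_rois = informative_rois, effect_sizes = d,
                 noise_sd = noise_sd, seed = seed,
                 n_per_group = n_per_group)),
    class = "mkl_cohort")
}

#' Default confound configuration
#'
#' A performance-IQ-like scaled score (block design: TR above DD) and an
#' inattention-like T-score (DSM-IV inattention: DD above TR), with group
#' means and SDs taken from the descriptive statistics of the study sample,
#' and a modest default loading of 0.1 noise-SD per covariate SD.
#'
#' @return Named list usable as `confound_effects` in [simulate_cohort()].
#' @export
default_confounds <- function() {
  list(
    performance_iq = list(mean_dd = 11.82, mean_tr = 14.18, sd = 2.9,
                          loading = 0.1),
    inattention = list(mean_dd = 60.09, mean_tr = 46.11, sd = 8.5,
                       loading = -0.1))
}

#' @export
print.mkl_cohort <- function(x, ...) {
  d <- dim(x$features)
  cat("Synthetic ROI cohort:", d[1L], "subjects x", d[2L], "ROIs x", d[3L],
      "contrasts\n")
  cat("  DD (+1):", sum(x$labels == 1), "  TR (-1):", sum(x$labels == -1),
      "\n")
  cat("  informative ROIs:",
      if (length(x$truth$informative_rois))
        paste(x$truth$informative_rois, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Simulate a BOLD run from a task design
#'
#' Builds the HRF-convolved condition regressors of `design`, multiplies by
#' planted per-condition amplitudes, optionally adds a linear drift, and adds
#' Gaussian noise. Sampling interval is the repetition time (default 2 s).
#'
#' @param design a [task_design()] object.
#' @param amplitudes named vector (one run unit) or units x conditions matrix
#'   of planted response amplitudes; names/columns must match the design's
#'   conditions.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param tr repetition time in seconds.
#' @param drift slope of an optional linear drift per volume (default 0).
#' @param seed RNG seed.
#' @return Object of class `"bold_run"` with `series` (units x volumes),
#'   `tr`, `amplitudes`, `design`.
#' @export
simulate_bold_run <- function(design, amplitudes, noise_sd = 0, tr = 2,
                              drift = 0, seed = 1L) {
  stopifnot(inherits(design, "task_design"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(dim(amplitudes)))
    amplitudes <- matrix(amplitudes, nrow = 1L,
                         dimnames = list(NULL, names(amplitudes)))
  if (is.null(colnames(amplitudes)) ||
      !setequal(colnames(amplitudes), design$conditions))
    stop("amplitudes must be named by the design conditions")
  amplitudes <- amplitudes[, design$conditions, drop = FALSE]
  n_volumes <- as.integer(ceiling(design$total_duration / tr))
  X <- design_matrix(design, n_volumes, tr = tr)
  Xc <- X[, design$conditions, drop = FALSE]
  set.seed(seed)
  series <- amplitudes %*% t(Xc)
  if (drift != 0)
    series <- series + rep(drift * (seq_len(n_volumes) - 1L),
                           each = nrow(series))
  if (noise_sd > 0)
    series <- series + matrix(rnorm(length(series), sd = noise_sd),
                              nrow = nrow(series))
  structure(list(series = series, tr = tr, amplitudes = amplitudes,
                 design = design, n_volumes = n_volumes),
            class = "bold_run")
}

#' Simulate a motion/intensity trace with planted outlier volumes
#'
#' Displacement is the scalar motion from the previous volume (mm; first
#' volume 0). Baseline displacements stay below 0.5 mm; requested motion
#' outliers exceed the 2 mm flagging threshold. Intensity outliers are
#' planted as level shifts so that only the requested volume shows a large
#' previous-volume difference.
#'
#' @param n_volumes number of volumes (>= 2).
#' @param outlier_volumes 1-based volume indices to plant motion outliers at
#'   (index 1 not allowed: the first volume has no predecessor).
#' @param intensity_outliers 1-based volume indices at which the mean
#'   intensity jumps and then decays back to baseline over the following
#'   volumes (index 1 not allowed). The decay keeps the whole-run SD small
#'   enough that only the jump itself crosses the 2.5-SD difference rule.
#' @param seed RNG seed.
#' @return Object of class `"motion_trace"`: list with `displacement` and
#'   `mean_intensity`, each of length `n_volumes`.
#' @export
simulate_motion_trace <- function(n_volumes, outlier_volumes = integer(),
                                  intensity_outliers = integer(),
                                  seed = 1L) {
  stopifnot(n_volumes >= 2L)
  outlier_volumes <- as.integer(outlier_volumes)
  intensity_outliers <- as.integer(intensity_outliers)
  if (any(outlier_volumes == 1L) || any(intensity_outliers == 1L))
    stop("volume 1 cannot be an outlier: it has no previous volume")
  if (any(outlier_volumes > n_volumes) ||
      any(intensity_outliers > n_volumes))
    stop("outlier index beyond the run length")
  set.seed(seed)
  displacement <- c(0, pmin(abs(rnorm(n_volumes - 1L, sd = 0.1)), 0.45))
  displacement[outlier_volumes] <- runif(length(outlier_volumes), 2.5, 3.5)
  mean_intensity <- 1000 + rnorm(n_volumes, sd = 1)
  if (length(intensity_outliers)) {
    k <- length(intensity_outliers)
    jump <- 50
    decay <- max(4L, min(15L, floor(0.4 * n_volumes / k)))
    bump <- rep(0, n_volumes)
    for (v in sort(intensity_outliers)) {
      len <- min(decay, n_volumes - v + 1L)
      bump[v:(v + len - 1L)] <- bump[v:(v + len - 1L)] +
        jump * (1 - (seq_len(len) - 1L) / decay)
    }
    mean_intensity <- mean_intensity + bump
  }
  structure(list(displacement = displacement,
                 mean_intensity = mean_intensity),
            class = "motion_trace")
}

#' Simulate a neuropsychological score table
#'
#' Draws per-subject Gaussian scores for a set of measures from per-group
#' means and SDs (e.g. the descriptive statistics shipped in
#' `table1_summary()`), one row per subject.
#'
#' @param measures data frame with columns `measure`, `dd_mean`, `dd_sd`,
#'   `tr_mean`, `tr_sd` (the format returned by [table1_summary()]).
#' @param n_per_group subjects per group.
#' @param seed RNG seed.
#' @return Data frame with `subject`, `group` (`"DD"`/`"TR"`), and one
#'   column per measure.
#' @export
simulate_neuropsych <- function(measures = table1_summary(),
                                n_per_group = 22L, seed = 1L) {
  stopifnot(all(c("measure", "dd_mean", "dd_sd", "tr_mean", "tr_sd") %in%
                names(measures)))
  if (any(measures$dd_sd < 0, na.rm = TRUE) ||
      any(measures$tr_sd < 0, na.rm = TRUE))
    stop("standard deviations must be non-negative")
  n <- 2L * n_per_group
  out <- data.frame(subject = sprintf("sub-%03d", seq_len(n)),
                    group = rep(c("DD", "TR"), each = n_per_group))
  set.seed(seed)
  for (i in seq_len(nrow(measures))) {
    m <- measures[i, ]
    out[[m$measure]] <- c(rnorm(n_per_group, m$dd_mean, m$dd_sd),
                          rnorm(n_per_group, m$tr_mean, m$tr_sd))
  }
  out
}

#' Write / read a cohort as tidy CSV plus a JSON truth sidecar
#'
#' One row per subject x ROI x contrast with columns `subject_id`, `group`,
#' `roi`, `contrast`, `value`, plus `covariates.csv` and `truth.json`.
#'
#' @param cohort an `"mkl_cohort"` object.
#' @param dir output directory (created if needed).
#' @return `write_cohort` invisibly returns the directory; `read_cohort`
#'   returns the reconstructed `"mkl_cohort"`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mkl_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(cohort$features)
  dn <- dimnames(cohort$features)
  tidy <- data.frame(
    subject_id = rep(dn[[1L]], times = d[2L] * d[3L]),
    group = rep(ifelse(cohort$labels == 1, "DD", "TR"),
                times = d[2L] * d[3L]),
    roi = rep(rep(dn[[2L]], each = d[1L]), times = d[3L]),
    contrast = rep(dn[[3L]], each = d[1L] * d[2L]),
    value = as.vector(cohort$features))
  write.csv(tidy, file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(cbind(subject_id = dn[[1L]], cohort$covariates),
            file.path(dir, "covariates.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  tidy <- read.csv(file.path(dir, "features.csv"))
  subjects <- unique(tidy$subject_id)
  rois <- unique(tidy$roi)
  contrasts <- unique(tidy$contrast)
  features <- array(tidy$value,
                    dim = c(length(subjects), length(rois),
                            length(contrasts)),
                    dimnames = list(subjects, rois, contrasts))
  labels <- ifelse(tidy$group[match(subjects, tidy$subject_id)] == "DD",
                   1, -1)
  covariates <- read.csv(file.path(dir, "covariates.csv"))
  covariates <- covariates[match(subjects, covariates$subject_id), -1L,
                           drop = FALSE]
  rownames(covariates) <- NULL
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  if (!is.null(truth$effect_sizes))
    truth$effect_sizes <- matrix(unlist(truth$effect_sizes),
                                 nrow = length(truth$informative_rois))
  structure(list(features = features, labels = labels,
                 covariates = covariates, truth = truth),
            class = "mkl_cohort")
}
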