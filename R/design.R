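#' Build a pseudorandom visual task design
#'
#' Two designs are available. `"gratings"`: 28 blocks (8 magnocellular M, 8
#' parvocellular P, 12 blank), each 14 s of stimulation followed by a 4 s
#' question period and a 2 s inter-stimulus period, ordered pseudorandomly
#' under the constraint that the same block type never appears in adjacent
#' blocks; gratings cycle through 6 orientations (0 to 150 degrees in 30
#' degree steps) every 2.33 s within a block. `"coherent_motion"`: 48
#' radial-motion trials (8 repetitions of each coherence level 6/15/40%
#' crossed with expanding/contracting direction), each 0.5 s fixation +
#' 0.25 s stimulus + 4 s response window + 4.25 s inter-stimulus period,
#' under the constraint that the same coherence level never occupies more
#' than two adjacent trials.
#'
#' Sequences are drawn by constrained sequential sampling with restart on
#' dead ends, capped at 10000 attempts (an error is raised rather than
#' silently relaxing a constraint). Blank blocks, question/response windows
#' and inter-stimulus periods are unmodeled baseline; only stimulus events
#' enter the design matrix.
#'
#' @param name `"gratings"` or `"coherent_motion"`.
#' @param seed RNG seed.
#' @return Object of class `"task_design"`: list with `name`, `events`
#'   (data frame `onset`, `duration`, `trial_type`, and for coherent motion
#'   `direction`), `conditions` (modeled condition names), and
#'   `total_duration` in seconds.
#' @examples
#' d <- task_design("gratings", seed = 3)
#' table(d$events$trial_type)
#' @export
task_design <- function(name = c("gratings", "coherent_motion"),
                        seed = 1L) {
  name <- match.arg(name)
  set.seed(seed)
  if (name == "gratings") {
    types <- c(M = 8L, P = 8L, blank = 12L)
    seq_types <- sample_no_repeat(types, max_run = 1L)
    block_len <- 14 + 4 + 2  # stimulus + question + inter-stimulus
    onsets <- (seq_along(seq_types) - 1L) * block_len
    events <- data.frame(onset = onsets, duration = 14,
                         trial_type = seq_types)
    structure(list(name = name, events = events, conditions = c("M", "P"),
                   n_blocks = length(seq_types),
                   orientations = c(0, 30, 60, 90, 120, 150),
                   orientation_step_s = 2.33,
                   block_structure = c(stimulus = 14, question = 4,
                                       isi = 2),
                   total_duration = length(seq_types) * block_len,
                   seed = seed),
              class = "task_design")
  } else {
    coh <- c(CML6 = 16L, CML15 = 16L, CML40 = 16L)
    seq_coh <- sample_no_repeat(coh, max_run = 2L)
    # balanced directions within each coherence level, shuffled
    direction <- character(length(seq_coh))
    for (lev in names(coh)) {
      idx <- which(seq_coh == lev)
      direction[idx] <- sample(rep(c("expanding", "contracting"),
                                   length(idx) / 2L))
    }
    trial_len <- 0.5 + 0.25 + 4 + 4.25
    trial_start <- (seq_along(seq_coh) - 1L) * trial_len
    events <- data.frame(onset = trial_start + 0.5, duration = 0.25,
                         trial_type = seq_coh, direction = direction)
    structure(list(name = name, events = events,
                   conditions = c("CML6", "CML15", "CML40"),
                   coherence_levels = c(CML6 = 0.06, CML15 = 0.15,
                                        CML40 = 0.40),
                   n_trials = length(seq_coh),
                   trial_structure = c(fixation = 0.5, stimulus = 0.25,
                                       response = 4, isi = 4.25),
                   total_duration = length(seq_coh) * trial_len,
                   seed = seed),
              class = "task_design")
  }
}

# Sample a permutation of a typed multiset such that no type occupies more
# than max_run adjacent slots; restart on dead end, capped at max_tries.
sample_no_repeat <- function(counts, max_run, max_tries = 10000L) {
  n <- sum(counts)
  for (try in seq_len(max_tries)) {
    remaining <- counts
    out <- character(n)
    ok <- TRUE
    for (i in seq_len(n)) {
      run <- 0L
      if (i > 1L) {
        j <- i - 1L
        while (j >= 1L && out[j] == out[i - 1L]) { run <- run + 1L; j <- j - 1L }
      }
      allowed <- names(remaining)[remaining > 0L]
      if (i > 1L && run >= max_run)
        allowed <- setdiff(allowed, out[i - 1L])
      if (!length(allowed)) { ok <- FALSE; break }
      pick <- if (length(allowed) == 1L) allowed
              else sample(allowed, 1L, prob = remaining[allowed])
      out[i] <- pick
      remaining[pick] <- remaining[pick] - 1L
    }
    if (ok) return(out)
  }
  stop("could not build a constraint-satisfying sequence in ", max_tries,
       " attempts")
}

#' @export
print.task_design <- function(x, ...) {
  cat("Task design '", x$name, "': ", nrow(x$events), " events, ",
      x$total_duration, " s\n", sep = "")
  print(table(x$events$trial_type))
  invisible(x)
}

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (response peaking near `peak_delay`
#' seconds minus an undershoot near `undershoot_delay` seconds scaled by
#' `ratio`), normalized to a peak of 1.
#'
#' @param t time in seconds (vector).
#' @param peak_delay,undershoot_delay gamma shape parameters (s).
#' @param dispersion,u_dispersion gamma scale parameters (s).
#' @param ratio undershoot amplitude relative to the peak (default 1/6).
#' @return Numeric vector of HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             dispersion = 1, u_dispersion = 1,
                             ratio = 1 / 6) {
  if (peak_delay <= 0 || undershoot_delay <= 0 || dispersion <= 0 ||
      u_dispersion <= 0)
    stop("HRF delays and dispersions must be positive")
  dg <- function(tt)
    dgamma(tt, shape = peak_delay / dispersion, scale = dispersion) -
      ratio * dgamma(tt, shape = undershoot_delay / u_dispersion,
                     scale = u_dispersion)
  h <- dg(t)
  h[t < 0] <- 0
  h / max(dg(seq(0, 50, by = 0.01)))
}

#' Build an HRF-convolved first-level design matrix
#'
#' One column per modeled task condition (stimulus boxcar convolved with the
#' canonical double-gamma HRF, sampled at volume acquisition times), any
#' nuisance regressors appended unmodified, and an intercept. Volume `i`
#' (1-based in R) is sampled at `(i - 1) * tr` seconds from run start.
#' Blank/fixation periods are implicit baseline and get no column.
#'
#' @param design a `"task_design"`.
#' @param n_volumes number of volumes; `n_volumes * tr` must cover the
#'   design duration.
#' @param tr repetition time in seconds (default 2).
#' @param hrf_params optional named list passed to [hrf_double_gamma()].
#' @param nuisance optional `n_volumes x k` matrix of nuisance regressors
#'   (e.g. motion parameters, [spike_regressors()] output).
#' @param dt convolution grid step in seconds.
#' @return `n_volumes x p` design matrix with named columns, intercept
#'   last. Errors if the assembled matrix is rank deficient (naming the
#'   collinear columns).
#' @export
design_matrix <- function(design, n_volumes, tr = 2, hrf_params = list(),
                          nuisance = NULL, dt = 0.1) {
  stopifnot(inherits(design, "task_design"))
  if (n_volumes * tr < design$total_duration)
    stop("n_volumes * tr does not cover the task duration")
  t_end <- n_volumes * tr + 32
  grid <- seq(0, t_end, by = dt)
  hrf <- do.call(hrf_double_gamma, c(list(t = seq(0, 32, by = dt)),
                                     hrf_params))
  vol_times <- (seq_len(n_volumes) - 1L) * tr
  cols <- list()
  for (cond in design$conditions) {
    ev <- design$events[design$events$trial_type == cond, , drop = FALSE]
    box <- numeric(length(grid))
    for (i in seq_len(nrow(ev))) {
      on <- ev$onset[i]
      box[grid >= on & grid < on + ev$duration[i]] <- 1
    }
    conv <- convolve(box, rev(hrf), type = "open")[seq_along(grid)] * dt
    cols[[cond]] <- approx(grid, conv, xout = vol_times, rule = 2)$y
  }
  X <- do.call(cbind, cols)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_volumes)
      stop("nuisance regressors must have n_volumes rows")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, nuisance)
  }
  X <- cbind(X, intercept = 1)
  nonzero <- colSums(abs(X)) > 0
  Xnz <- X[, nonzero, drop = FALSE]
  qrX <- qr(Xnz)
  if (qrX$rank < ncol(Xnz)) {
    bad <- colnames(Xnz)[qrX$pivot[(qrX$rank + 1L):ncol(Xnz)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Fit per-unit ordinary least squares GLMs
#'
#' Plain OLS of each unit's time series on the design matrix, with no
#' autocorrelation correction.
#'
#' @param bold a `"bold_run"` (or any units x volumes matrix via `series`).
#' @param X design matrix from [design_matrix()].
#' @return Object of class `"glm_fit"`: list with `betas` (units x
#'   regressors), `sigma2` (per-unit residual variance), `df_residual`,
#'   `task` (design name).
#' @export
fit_glm <- function(bold, X) {
  series <- if (inherits(bold, "bold_run")) bold$series else as.matrix(bold)
  if (any(!is.finite(series))) stop("BOLD series contains non-finite values")
  if (ncol(series) != nrow(X))
    stop("volume count mismatch between series and design matrix")
  fit <- lm.fit(X, t(series))
  betas <- t(as.matrix(fit$coefficients))
  colnames(betas) <- colnames(X)
  res <- as.matrix(fit$residuals)
  dfres <- nrow(X) - fit$rank
  sigma2 <- colSums(res^2) / max(dfres, 1L)
  structure(list(betas = betas, sigma2 = sigma2, df_residual = dfres,
                 task = if (inherits(bold, "bold_run"))
                   bold$design$name else NA_character_),
            class = "glm_fit")
}

#' Versus-baseline contrast maps from fitted GLM betas
#'
#' With blank/fixation as implicit baseline, each versus-baseline contrast
#' is the condition beta itself. The gratings task yields `M-vs-B` and
#' `P-vs-B`; the coherent motion task yields `CML6-vs-B`, `CML15-vs-B`,
#' `CML40-vs-B`; their union is the fixed set of five per subject.
#'
#' @param fit a `"glm_fit"` (or a units x regressors beta matrix).
#' @param task `"gratings"` or `"coherent_motion"`; taken from `fit` if
#'   available.
#' @return Units x contrasts matrix with contrast names as columns.
#' @export
compute_contrasts <- function(fit, task = NULL) {
  betas <- if (inherits(fit, "glm_fit")) fit$betas else as.matrix(fit)
  if (is.null(task) && inherits(fit, "glm_fit")) task <- fit$task
  conds <- switch(task,
    gratings = c("M" = "M-vs-B", "P" = "P-vs-B"),
    coherent_motion = c("CML6" = "CML6-vs-B", "CML15" = "CML15-vs-B",
                        "CML40" = "CML40-vs-B"),
    stop("unknown task '", task, "'"))
  missing <- setdiff(names(conds), colnames(betas))
  if (length(missing))
    stop("betas lack condition columns: ", paste(missing, collapse = ", "))
  out <- betas[, names(conds), drop = FALSE]
  colnames(out) <- unname(conds)
  out
}
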