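test_that("gratings design has 28 blocks (8 M, 8 P, 12 blank), none adjacent", {
  for (s in 1:5) {
    d <- task_design("gratings", seed = s)
    tab <- table(d$events$trial_type)
    expect_equal(unname(tab[c("M", "P", "blank")]), c(8L, 8L, 12L),
                 ignore_attr = TRUE)
    expect_equal(nrow(d$events), 28)
    types <- d$events$trial_type
    expect_false(any(types[-1] == types[-length(types)]))
    expect_equal(d$total_duration, 28 * 20)
  }
})

test_that("gratings orientation schedule covers a block in 6 steps", {
  d <- task_design("gratings", seed = 1)
  expect_equal(d$orientations, seq(0, 150, by = 30))
  expect_equal(length(d$orientations) * d$orientation_step_s, 13.98,
               tolerance = 0.005)
  expect_equal(unname(d$block_structure["stimulus"]), 14)
})

test_that("coherent motion design: 48 trials, 8 per coherence x direction,
          no coherence level three in a row", {
  for (s in 1:5) {
    d <- task_design("coherent_motion", seed = s)
    expect_equal(nrow(d$events), 48)
    tab <- table(d$events$trial_type, d$events$direction)
    expect_true(all(tab == 8))
    expect_equal(sort(unname(d$coherence_levels)), c(0.06, 0.15, 0.40))
    lev <- d$events$trial_type
    for (i in 1:(length(lev) - 2))
      expect_gte(length(unique(lev[i:(i + 2)])), 2)
    expect_equal(d$total_duration, 48 * 9)
  }
})

test_that("designs are reproducible under seed", {
  expect_identical(task_design("gratings", seed = 3)$events,
                   task_design("gratings", seed = 3)$events)
  expect_identical(task_design("coherent_motion", seed = 3)$events,
                   task_design("coherent_motion", seed = 3)$events)
})

test_that("constraint sampler errors out rather than relaxing", {
  expect_error(roimkl:::sample_no_repeat(c(a = 5L, b = 1L), max_run = 1L,
                                         max_tries = 50L),
               "constraint")
})

test_that("HRF is a positive-peaked double gamma with undershoot", {
  t <- seq(0, 32, by = 0.1)
  h <- hrf_double_gamma(t)
  expect_equal(max(h), 1, tolerance = 1e-6)
  expect_equal(t[which.max(h)], 5, tolerance = 0.5)
  expect_lt(min(h), 0)          # undershoot present
  expect_equal(h[t < 0], numeric(0))
  expect_error(hrf_double_gamma(t, peak_delay = -1), "positive")
})

test_that("design-matrix columns equal a brute-force convolution", {
  d <- structure(list(name = "gratings",
                      events = data.frame(onset = 0, duration = 14,
                                          trial_type = "M"),
                      conditions = "M", total_duration = 100),
                 class = "task_design")
  X <- design_matrix(d, n_volumes = 50, tr = 2)
  times <- (0:49) * 2
  oracle <- convolve_boxcar_oracle(0, 14, hrf_double_gamma, times)
  expect_equal(unname(X[, "M"]), oracle, tolerance = 0.02)
  # response rises after onset and peaks after the stimulus is underway
  pk <- times[which.max(X[, "M"])]
  expect_gt(pk, 4)
  expect_lt(pk, 20)
  expect_equal(unname(X[1, "M"]), 0, tolerance = 1e-8)
})

test_that("convolution is linear in the event set", {
  one <- function(onset) structure(
    list(name = "g", events = data.frame(onset = onset, duration = 14,
                                         trial_type = "M"),
         conditions = "M", total_duration = 200), class = "task_design")
  both <- structure(
    list(name = "g", events = data.frame(onset = c(0, 60), duration = 14,
                                         trial_type = "M"),
         conditions = "M", total_duration = 200), class = "task_design")
  Xa <- design_matrix(one(0), 100, tr = 2)
  Xb <- design_matrix(one(60), 100, tr = 2)
  Xab <- design_matrix(both, 100, tr = 2)
  expect_equal(Xab[, "M"], Xa[, "M"] + Xb[, "M"], tolerance = 1e-10)
})

test_that("task column counts match the two protocols", {
  g <- task_design("gratings", seed = 1)
  cm <- task_design("coherent_motion", seed = 1)
  Xg <- design_matrix(g, ceiling(g$total_duration / 2), tr = 2)
  Xc <- design_matrix(cm, ceiling(cm$total_duration / 2), tr = 2)
  expect_equal(setdiff(colnames(Xg), "intercept"), c("M", "P"))
  expect_equal(setdiff(colnames(Xc), "intercept"),
               c("CML6", "CML15", "CML40"))
})

test_that("an empty design yields intercept plus nuisance only", {
  d <- structure(list(name = "none", events = data.frame(),
                      conditions = character(0), total_duration = 0),
                 class = "task_design")
  X <- design_matrix(d, 10, tr = 2)
  expect_equal(colnames(X), "intercept")
  nuis <- matrix(rnorm(10), 10, 1, dimnames = list(NULL, "motion1"))
  X2 <- design_matrix(d, 10, tr = 2, nuisance = nuis)
  expect_equal(colnames(X2), c("motion1", "intercept"))
})

test_that("rank-deficient designs error naming the collinear columns", {
  d <- task_design("gratings", seed = 1)
  nv <- ceiling(d$total_duration / 2)
  bad <- matrix(1, nv, 1, dimnames = list(NULL, "constant_copy"))
  expect_error(design_matrix(d, nv, tr = 2, nuisance = bad),
               "collinear")
})

test_that("GLM recovers planted amplitudes exactly without noise", {
  des <- task_design("coherent_motion", seed = 2)
  amp <- c(CML6 = 1.0, CML15 = 0.5, CML40 = 0.2)
  run <- simulate_bold_run(des, amp, noise_sd = 0)
  X <- design_matrix(des, run$n_volumes, tr = 2)
  fit <- fit_glm(run, X)
  expect_lt(max(abs(fit$betas[, names(amp)] - amp)), 1e-10)
  expect_lt(abs(fit$betas[, "intercept"]), 1e-10)
})

test_that("GLM estimates are unbiased under noise", {
  des <- task_design("gratings", seed = 3)
  nv <- ceiling(des$total_duration / 2)
  X <- design_matrix(des, nv, tr = 2)
  est <- matrix(NA_real_, 200, 2)
  for (r in 1:200) {
    run <- simulate_bold_run(des, c(M = 2.0, P = 0.5), noise_sd = 0.5,
                             seed = 1000 + r)
    est[r, ] <- fit_glm(run, X)$betas[, c("M", "P")]
  }
  se <- apply(est, 2, sd) / sqrt(200)
  expect_lt(abs(mean(est[, 1]) - 2.0), 2 * se[1] + 1e-8)
  expect_lt(abs(mean(est[, 2]) - 0.5), 2 * se[2] + 1e-8)
})

test_that("contrasts are the condition betas and invariant to offsets", {
  des <- task_design("gratings", seed = 5)
  run <- simulate_bold_run(des, c(M = 1.0, P = 0.2), noise_sd = 0)
  X <- design_matrix(des, run$n_volumes, tr = 2)
  cm <- compute_contrasts(fit_glm(run, X))
  expect_equal(colnames(cm), c("M-vs-B", "P-vs-B"))
  expect_equal(unname(cm[1, ]), c(1.0, 0.2), tolerance = 1e-10)
  run2 <- run
  run2$series <- run2$series + 57
  cm2 <- compute_contrasts(fit_glm(run2, X))
  expect_equal(cm, cm2, tolerance = 1e-9)
  expect_error(compute_contrasts(fit_glm(run, X), task = "nope"),
               "unknown task")
})

test_that("the two tasks together span the five contrast maps", {
  g <- compute_contrasts(matrix(0, 1, 3,
                                dimnames = list(NULL, c("M", "P",
                                                        "intercept"))),
                         task = "gratings")
  cm <- compute_contrasts(matrix(0, 1, 4,
                                 dimnames = list(NULL, c("CML6", "CML15",
                                                         "CML40",
                                                         "intercept"))),
                          task = "coherent_motion")
  expect_equal(c(colnames(g), colnames(cm)), CONTRAST_NAMES)
})

test_that("noise sweep: contrast recovery error shrinks with noise", {
  des <- task_design("gratings", seed = 6)
  X <- design_matrix(des, ceiling(des$total_duration / 2), tr = 2)
  rmse <- sapply(c(1, 0.1, 0), function(s) {
    run <- simulate_bold_run(des, c(M = 1, P = 0.4), noise_sd = s,
                             seed = 11)
    sqrt(mean((compute_contrasts(fit_glm(run, X))[1, ] - c(1, 0.4))^2))
  })
  expect_true(all(diff(rmse) <= 1e-12))
  expect_lt(rmse[3], 1e-10)
})
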