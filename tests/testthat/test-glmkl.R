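test_that("per-ROI kernels are hand-verifiable standardized Grams", {
  X <- matrix(c(1, 2, 3,
                0, 1, -1,
                2, 0, 1,
                1, 0, 1,
                -1, 1, 0), nrow = 3, ncol = 5)
  feats <- array(X, dim = c(3, 1, 5))
  ks <- build_roi_kernels(feats)
  Z <- scale(X)
  G <- tcrossprod(Z)
  G <- G * 3 / sum(diag(G))
  expect_equal(ks$kernels[[1]], G, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sum(diag(ks$kernels[[1]])), 3, tolerance = 1e-12)
})

test_that("kernel matrices are symmetric PSD and duplicate subjects
          duplicate rows", {
  coh <- toy_cohort(n_per_group = 6, n_rois = 4, seed = 3)
  f <- coh$features
  f[2, , ] <- f[1, , ]  # duplicate subject
  ks <- build_roi_kernels(f)
  for (K in ks$kernels) {
    expect_equal(K, t(K), tolerance = 1e-12)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    expect_equal(K[1, ], K[2, ], tolerance = 1e-12)
  }
  expect_equal(length(ks$kernels), 4)
})

test_that("zero-variance features are dropped with a warning", {
  coh <- toy_cohort(n_per_group = 4, n_rois = 2, seed = 1)
  coh$features[, 1, 2] <- 5
  expect_warning(build_roi_kernels(coh$features), "zero-variance")
})

test_that("a single-kernel MKL fit degenerates to a plain SVM", {
  set.seed(10)
  for (rep in 1:5) {
    n <- 14
    feats <- array(rnorm(n * (n + 4)), dim = c(n, 1, n + 4))
    y <- rep(c(1, -1), each = n / 2)
    fit <- glmkl(feats, y, C = 2, p = 1.05)
    expect_equal(unname(fit$beta), 1)
    oracle <- svc_pg_oracle(fit$kernels$kernels[[1]], y, 2)
    expect_lt(max(abs(predict(fit, type = "decision") - oracle$decision)),
              1e-6)
  }
})

test_that("trained models satisfy the KKT and norm constraints", {
  for (s in 1:3) {
    coh <- toy_cohort(n_per_group = 8, n_rois = 5, seed = s)
    for (hp in list(c(0.5, 1.05), c(1, 2), c(8, 4))) {
      fit <- glmkl(coh$features, coh$labels, C = hp[1], p = hp[2])
      expect_true(all(fit$beta >= 0))
      expect_lt(abs(sum(fit$beta^fit$p)^(1 / fit$p) - 1), 1e-8)
      expect_true(all(fit$alpha >= -1e-9 & fit$alpha <= hp[1] + 1e-9))
      expect_lt(abs(sum(fit$alpha * fit$y)), 1e-8)
    }
  }
})

test_that("the alternation objective is monotone non-increasing", {
  for (s in 1:4) {
    coh <- toy_cohort(n_per_group = 10, n_rois = 8, seed = 20 + s)
    fit <- glmkl(coh$features, coh$labels, C = 1, p = 1.05)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-4 * (1 + abs(tr[-length(tr)]))))
  }
})

test_that("informative ROIs receive the largest kernel weights", {
  hits <- 0
  for (s in 1:100) {
    coh <- simulate_cohort(n_per_group = 20, n_rois = 10,
                           informative_rois = c(2, 7), effect_sizes = 3,
                           confound_effects = list(), seed = 300 + s)
    fit <- glmkl(coh$features, coh$labels, C = 1, p = 1.05)
    top2 <- order(fit$beta, decreasing = TRUE)[1:2]
    if (setequal(top2, c(2, 7))) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("alternating optimization matches an exhaustive weight search
          on a 3-kernel problem", {
  coh <- simulate_cohort(n_per_group = 10, n_rois = 3,
                         informative_rois = 1, effect_sizes = 2.5,
                         confound_effects = list(), seed = 77)
  p <- 2
  fit <- glmkl(coh$features, coh$labels, C = 1, p = p)
  Ks <- fit$kernels$kernels
  y <- fit$y
  # the quantity under cross-check is the weight path, not the dual
  # solver (checked elsewhere against the projected-gradient oracle), so
  # both routes may share the dual solver
  dual_at <- function(beta) {
    K <- beta[1] * Ks[[1]] + beta[2] * Ks[[2]] + beta[3] * Ks[[3]]
    o <- roimkl:::cpp_svc(K, y, 1, eps = 1e-10)
    sum(o$alpha) - 0.5 * sum((o$alpha * y) * (K %*% (o$alpha * y)))
  }
  g <- seq(0.02, 1, by = 0.04)
  best <- NULL; best_val <- Inf
  for (b1 in g) for (b2 in g) {
    rest <- 1 - b1^p - b2^p
    if (rest < 0) next
    beta <- c(b1, b2, rest^(1 / p))
    val <- dual_at(beta)
    if (val < best_val) { best_val <- val; best <- beta }
  }
  # the fitted weights are at least as good as the exhaustive grid optimum
  expect_lte(dual_at(unname(fit$beta)), best_val + 1e-4 * (1 + best_val))
  expect_lt(max(abs(unname(fit$beta) - best)), 0.08)
})

test_that("identical kernels share the weight uniformly (large-p limit)", {
  n <- 12
  set.seed(9)
  block <- matrix(rnorm(n * 5), n)
  feats <- array(rep(as.vector(block), 4), dim = c(n, 5, 4))
  feats <- aperm(feats, c(1, 3, 2))  # 4 identical ROIs
  y <- rep(c(1, -1), each = n / 2)
  fit <- glmkl(feats, y, C = 1, p = 4)
  expect_equal(unname(fit$beta), rep(4^(-1 / 4), 4), tolerance = 1e-3)
})

test_that("uniform frozen weights reproduce an SVM on the mean kernel", {
  coh <- toy_cohort(n_per_group = 7, n_rois = 5, seed = 13)
  ks <- build_roi_kernels(coh$features)
  n <- 14
  # the frozen-uniform combined kernel is the plain average
  Kbar <- Reduce(`+`, ks$kernels) / 5
  f <- roimkl:::cpp_mkl_train(array(Kbar, dim = c(n, n, 1)), coh$labels,
                              1, 1.05)
  oracle <- svc_pg_oracle(Kbar, coh$labels, 1)
  dec <- as.numeric(Kbar %*% (f$alpha * coh$labels)) + f$b
  expect_lt(max(abs(dec - oracle$decision)), 1e-6)
})

test_that("prediction follows the stated decision function, ties to TR", {
  coh <- toy_cohort(n_per_group = 5, n_rois = 3, seed = 4)
  fit <- glmkl(coh$features, coh$labels, C = 1, p = 2)
  new <- coh$features[3:4, , , drop = FALSE]
  Kx <- cross_roi_kernels(fit$kernels, new)
  f_hand <- rep(fit$b, 2)
  for (i in seq_along(fit$alpha))
    for (m in 1:3)
      f_hand <- f_hand + fit$alpha[i] * fit$y[i] * fit$beta[m] *
        c(Kx[[m]][1, i], Kx[[m]][2, i])
  expect_lt(max(abs(predict(fit, new, type = "decision") - f_hand)),
            1e-10)
  # tie handling: a zero decision value is assigned to TR (-1)
  fit0 <- fit
  fit0$alpha <- rep(0, length(fit0$alpha))
  fit0$b <- 0
  expect_equal(unique(predict(fit0, new)), -1)
})

test_that("a separable fit classifies its training set perfectly", {
  coh <- simulate_cohort(n_per_group = 8, n_rois = 4,
                         informative_rois = 1:2, effect_sizes = 6,
                         confound_effects = list(), seed = 6)
  fit <- glmkl(coh$features, coh$labels, C = 100, p = 2)
  expect_equal(predict(fit), coh$labels)
})

test_that("accuracy and AUC match brute-force definitions", {
  ev <- evaluate_classifier(c(1, 1, -1, -1), c(0.9, 0.8, 0.3, 0.1),
                            c(1, -1, 1, -1))
  expect_equal(ev$accuracy, 0.5)
  expect_equal(ev$auc, 0.75)
  expect_equal(auc_bruteforce(c(0.9, 0.8, 0.3, 0.1), c(1, -1, 1, -1)),
               0.75)
  ev2 <- evaluate_classifier(c(1, -1), c(2, -2), c(1, -1))
  expect_equal(ev2$accuracy, 1)
  set.seed(8)
  dec <- rnorm(60)
  y <- rep(c(1, -1), 30)
  expect_equal(evaluate_classifier(sign(dec), dec, y)$auc,
               auc_bruteforce(dec, y))
  expect_error(evaluate_classifier(c(1, 1), c(1, 2), c(1, 1)), "absent")
  # large-sample null AUC approaches one half
  set.seed(9)
  decn <- rnorm(2000)
  yn <- rep(c(1, -1), 1000)
  expect_lt(abs(evaluate_classifier(sign(decn), decn, yn)$auc - 0.5),
            0.05)
})
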