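# Independent numerical oracles used across the suite. These never share
# code with the package's solvers.

# C-SVM dual by projected gradient descent with exact projection onto the
# box-and-hyperplane feasible set (bisection on the hyperplane multiplier).
# Converges linearly for positive-definite kernels; run tight.
svc_pg_oracle <- function(K, y, C, iters = 200000, tol = 1e-13) {
  n <- length(y)
  Q <- (y %o% y) * K
  L <- max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / L
  proj <- function(v) {
    f <- function(l) sum(y * pmin(pmax(v - l * y, 0), C))
    lo <- -max(abs(v)) - C - 1
    hi <- -lo
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    pmin(pmax(v - ((lo + hi) / 2) * y, 0), C)
  }
  a <- proj(rep(C / 2, n))
  for (i in seq_len(iters)) {
    g <- Q %*% a - 1
    a2 <- proj(a - step * g)
    if (max(abs(a2 - a)) < tol) {
      a <- a2
      break
    }
    a <- a2
  }
  a <- as.numeric(a)
  # bias: mean KKT value over free vectors, else midpoint of the violating
  # bound interval
  val <- as.numeric(y - K %*% (a * y))
  tb <- 1e-7 * C
  free <- a > tb & a < C - tb
  b <- if (any(free)) {
    mean(val[free])
  } else {
    up <- (y > 0 & a < C - tb) | (y < 0 & a > tb)
    low <- (y > 0 & a > tb) | (y < 0 & a < C - tb)
    (max(val[up]) + min(val[low])) / 2
  }
  list(alpha = a, b = b,
       decision = as.numeric(K %*% (a * y)) + b)
}

# Brute-force AUC: fraction of (positive, negative) pairs ranked correctly,
# ties counted one half.
auc_bruteforce <- function(decision, labels) {
  pos <- decision[labels == 1]
  neg <- decision[labels == -1]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Riemann-sum convolution of a boxcar with a kernel, sampled at arbitrary
# times (oracle for the design-matrix column construction).
convolve_boxcar_oracle <- function(onsets, durations, hrf_fun, times,
                                   dt = 0.01) {
  grid <- seq(0, max(times) + 40, by = dt)
  box <- numeric(length(grid))
  for (i in seq_along(onsets))
    box[grid >= onsets[i] & grid < onsets[i] + durations[i]] <- 1
  out <- numeric(length(times))
  for (k in seq_along(times)) {
    tk <- times[k]
    idx <- which(grid <= tk)
    out[k] <- sum(box[idx] * hrf_fun(tk - grid[idx]) * dt)
  }
  out
}

# A small separable / planted cohort for classifier tests.
toy_cohort <- function(n_per_group = 8, n_rois = 6, informative = 1,
                       d = 2, seed = 1) {
  simulate_cohort(n_per_group = n_per_group, n_rois = n_rois,
                  informative_rois = informative, effect_sizes = d,
                  confound_effects = list(), seed = seed)
}

# Exact mean of a noncentral t with df nu and noncentrality delta.
noncentral_t_mean <- function(delta, nu) {
  delta * sqrt(nu / 2) * exp(lgamma((nu - 1) / 2) - lgamma(nu / 2))
}
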