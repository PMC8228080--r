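// Core numerical routines: C-SVM dual solver (SMO), lp-norm multiple kernel
// learning by alternating optimization, and the cross-validation inner loop.
// Kept in C++ because permutation tests and backward elimination need on the
// order of 1e5 MKL fits.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct SvcFit {
  vec alpha;
  double b;
  double obj;      // dual objective, maximization form
  int iter;
};

// SMO with maximal-violating-pair working-set selection for
//   max  e'a - 1/2 a'Qa,  Q_ij = y_i y_j K_ij,  0 <= a <= C,  y'a = 0.
static SvcFit smo_solve(const mat& K, const vec& y, double C,
                        double eps = 1e-10, int max_iter = 500000,
                        const vec* warm = nullptr) {
  const int n = K.n_rows;
  vec alpha(n, fill::zeros);
  vec G(n, fill::value(-1.0));  // G = Q*alpha - e
  if (warm && warm->n_elem == (uword)n && accu(abs(*warm)) > 0) {
    alpha = *warm;
    alpha.clamp(0.0, C);
    // restore feasibility of y'alpha = 0 lost to kernel change/clamping
    double viol = dot(y, alpha);
    if (std::abs(viol) > 1e-12) {
      // shift mass off the class with excess, proportionally where possible
      for (int t = 0; t < n && std::abs(viol) > 1e-12; ++t) {
        double adj = y(t) * viol;  // amount to subtract from alpha_t
        if (adj > 0) { double d = std::min(adj, alpha(t)); alpha(t) -= d; viol -= y(t) * d; }
        else { double d = std::min(-adj, C - alpha(t)); alpha(t) += d; viol += y(t) * d; }
      }
    }
    G = (K * (alpha % y)) % y - 1.0;  // Q*alpha - e
  }
  int it = 0;
  for (; it < max_iter; ++it) {
    // select i in I_up maximizing -y*G, j in I_low minimizing -y*G
    int i = -1, j = -1;
    double m_up = -datum::inf, m_low = datum::inf;
    for (int t = 0; t < n; ++t) {
      double v = -y(t) * G(t);
      bool up  = (y(t) > 0) ? (alpha(t) < C) : (alpha(t) > 0);
      bool low = (y(t) > 0) ? (alpha(t) > 0) : (alpha(t) < C);
      if (up && v > m_up)  { m_up = v;  i = t; }
      if (low && v < m_low){ m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < eps) break;
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad < 1e-14) quad = 1e-14;
    double d = (m_up - m_low) / quad;  // = -(yG_i - yG_j)/quad >= 0
    // box limits: alpha_i += y_i d, alpha_j -= y_j d
    double dmax = (y(i) > 0) ? (C - alpha(i)) : alpha(i);
    double dj   = (y(j) > 0) ? alpha(j) : (C - alpha(j));
    if (dj < dmax) dmax = dj;
    if (d > dmax) d = dmax;
    if (d <= 0) break;
    alpha(i) += y(i) * d;
    alpha(j) -= y(j) * d;
    for (int t = 0; t < n; ++t)
      G(t) += y(t) * d * (K(t, i) - K(t, j));
  }
  // bias from free support vectors, else midpoint of the bound interval;
  // bound membership is judged with a tolerance so clamping dust does not
  // flip a bounded alpha into the "free" or "movable" sets
  const double tb = 1e-9 * C;
  double bsum = 0; int nfree = 0;
  for (int t = 0; t < n; ++t)
    if (alpha(t) > tb && alpha(t) < C - tb) { bsum += -y(t) * G(t); ++nfree; }
  double b;
  if (nfree > 0) b = bsum / nfree;
  else {
    double m_up = -datum::inf, m_low = datum::inf;
    for (int t = 0; t < n; ++t) {
      double v = -y(t) * G(t);
      bool up  = (y(t) > 0) ? (alpha(t) < C - tb) : (alpha(t) > tb);
      bool low = (y(t) > 0) ? (alpha(t) > tb) : (alpha(t) < C - tb);
      if (up && v > m_up) m_up = v;
      if (low && v < m_low) m_low = v;
    }
    b = 0.5 * (m_up + m_low);
  }
  // dual objective e'a - 1/2 a'Qa; note G = Qa - e so a'Qa = a'(G + e)
  double obj = accu(alpha) - 0.5 * dot(alpha, G + 1.0);
  SvcFit fit;
  fit.alpha = alpha; fit.b = b; fit.obj = obj; fit.iter = it;
  return fit;
}

struct MklFit {
  vec beta;
  vec alpha;
  double b;
  bool converged;
  int iters;
  vec obj_trace;
};

// Alternating lp-norm MKL: (i) SVM dual on K(beta) = sum beta_m K_m;
// (ii) closed-form update beta_m  ~  ||w_m||^(2/(p+1)) with ||beta||_p = 1,
// where ||w_m||^2 = beta_m^2 (a.y)' K_m (a.y).
// Kflat holds the R base kernels as columns of an (n*n) x R matrix so both
// the kernel combination and all R quadratic forms are single BLAS gemv
// calls per alternation.
static MklFit mkl_train_flat(const mat& Kflat, const vec& y, double C,
                             double p, double tol, int max_alt,
                             double svm_eps) {
  const int R = Kflat.n_cols;
  const int n = y.n_elem;
  vec beta(R, fill::value(std::pow((double)R, -1.0 / p)));
  MklFit out;
  out.converged = false;
  std::vector<double> trace;
  mat K(n, n);
  SvcFit svc;
  vec warm(n, fill::zeros);
  // intermediate alternations only steer the beta path; solve them at a
  // looser KKT tolerance and reserve the tight one for the final model
  double eps_alt = std::max(svm_eps, 1e-6);
  int a = 0;
  for (; a < max_alt; ++a) {
    K = reshape(Kflat * beta, n, n);
    svc = smo_solve(K, y, C, eps_alt, 500000, a > 0 ? &warm : nullptr);
    warm = svc.alpha;
    trace.push_back(svc.obj);
    vec ay = svc.alpha % y;
    vec q = Kflat.t() * vectorise(ay * ay.t());  // q_m = (a.y)' K_m (a.y)
    vec w2 = square(beta) % q;
    bool stop_now = false;
    if (R == 1) { beta(0) = 1.0; stop_now = true; }
    else if (w2.max() < 1e-14) stop_now = true;
    if (stop_now) {
      K = reshape(Kflat * beta, n, n);
      svc = smo_solve(K, y, C, svm_eps, 500000, &warm);
      trace.push_back(svc.obj);
      out.converged = true;
      ++a;
      break;
    }
    vec v = pow(w2, 1.0 / (p + 1.0));
    double norm_p = std::pow(accu(pow(v, p)), 1.0 / p);
    vec beta_new = v / norm_p;
    double delta = abs(beta_new - beta).max();
    beta = beta_new;
    if (delta < tol) {
      // final SVM solve at the converged weights
      K = reshape(Kflat * beta, n, n);
      svc = smo_solve(K, y, C, svm_eps, 500000, &warm);
      trace.push_back(svc.obj);
      out.converged = true;
      ++a;
      break;
    }
  }
  if (!out.converged) {  // tight solve at the last iterate
    K = reshape(Kflat * beta, n, n);
    svc = smo_solve(K, y, C, svm_eps, 500000, &warm);
    trace.push_back(svc.obj);
  }
  out.beta = beta;
  out.alpha = svc.alpha;
  out.b = svc.b;
  out.iters = a;
  out.obj_trace = vec(trace);
  return out;
}

static MklFit mkl_train(const cube& Ks, const vec& y, double C, double p,
                        double tol, int max_alt, double svm_eps) {
  const int n = y.n_elem;
  mat Kflat(const_cast<double*>(Ks.memptr()), n * n, Ks.n_slices, false,
            true);
  return mkl_train_flat(Kflat, y, C, p, tol, max_alt, svm_eps);
}

// Same alternation on linear kernels expressed in feature space:
// K_m = s_m A_m A_m' with A_m the m-th standardized feature block, so the
// combined kernel is one rank-d product of block-scaled features and
// ||w_m||^2 = beta_m^2 s_m ||A_m' (a.y)||^2. Avoids materializing the R
// base Gram matrices in the cross-validation hot path.
static MklFit mkl_train_feat(const mat& Xtr, const vec& scale,
                             const vec& y, int ncon, double C, double p,
                             double tol, int max_alt, double svm_eps) {
  const int R = scale.n_elem;
  const int n = y.n_elem;
  vec beta(R, fill::value(std::pow((double)R, -1.0 / p)));
  MklFit out;
  out.converged = false;
  std::vector<double> trace;
  mat Xb(n, Xtr.n_cols);
  SvcFit svc;
  vec warm(n, fill::zeros);
  double eps_alt = std::max(svm_eps, 1e-6);
  auto combined = [&](const vec& bt) {
    rowvec f(Xtr.n_cols);
    for (int m = 0; m < R; ++m)
      f.subvec(m * ncon, (m + 1) * ncon - 1)
          .fill(std::sqrt(bt(m) * scale(m)));
    Xb = Xtr.each_row() % f;
    return mat(Xb * Xb.t());
  };
  int a = 0;
  for (; a < max_alt; ++a) {
    mat K = combined(beta);
    svc = smo_solve(K, y, C, eps_alt, 500000, a > 0 ? &warm : nullptr);
    warm = svc.alpha;
    trace.push_back(svc.obj);
    vec ay = svc.alpha % y;
    vec pr = Xtr.t() * ay;  // per-feature projections, all ROIs at once
    vec w2(R);
    for (int m = 0; m < R; ++m)
      w2(m) = beta(m) * beta(m) * scale(m) *
        dot(pr.subvec(m * ncon, (m + 1) * ncon - 1),
            pr.subvec(m * ncon, (m + 1) * ncon - 1));
    bool stop_now = (R == 1) || (w2.max() < 1e-14);
    if (R == 1) beta(0) = 1.0;
    if (!stop_now) {
      vec v = pow(w2, 1.0 / (p + 1.0));
      double norm_p = std::pow(accu(pow(v, p)), 1.0 / p);
      vec beta_new = v / norm_p;
      double delta = abs(beta_new - beta).max();
      beta = beta_new;
      stop_now = delta < tol;
    }
    if (stop_now) {
      mat Kf = combined(beta);
      svc = smo_solve(Kf, y, C, svm_eps, 500000, &warm);
      trace.push_back(svc.obj);
      out.converged = true;
      ++a;
      break;
    }
  }
  if (!out.converged) {
    mat Kf = combined(beta);
    svc = smo_solve(Kf, y, C, svm_eps, 500000, &warm);
    trace.push_back(svc.obj);
  }
  out.beta = beta;
  out.alpha = svc.alpha;
  out.b = svc.b;
  out.iters = a;
  out.obj_trace = vec(trace);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_svc(const arma::mat& K, const arma::vec& y, double C,
                   double eps = 1e-10) {
  SvcFit f = smo_solve(K, y, C, eps);
  return Rcpp::List::create(Rcpp::Named("alpha") = f.alpha,
                            Rcpp::Named("b") = f.b,
                            Rcpp::Named("objective") = f.obj,
                            Rcpp::Named("iterations") = f.iter);
}

// [[Rcpp::export]]
Rcpp::List cpp_mkl_train(const arma::cube& Ks, const arma::vec& y, double C,
                         double p, double tol = 1e-4, int max_alt = 200,
                         double svm_eps = 1e-10) {
  MklFit f = mkl_train(Ks, y, C, p, tol, max_alt, svm_eps);
  return Rcpp::List::create(Rcpp::Named("beta") = f.beta,
                            Rcpp::Named("alpha") = f.alpha,
                            Rcpp::Named("b") = f.b,
                            Rcpp::Named("converged") = f.converged,
                            Rcpp::Named("iterations") = f.iters,
                            Rcpp::Named("objective_trace") = f.obj_trace);
}

// Standardize columns of X by train-row moments (sd denominator n-1);
// zero-variance columns are zeroed out.
static void standardize_train(const mat& X, const uvec& train,
                              mat& Xs) {
  Xs.set_size(X.n_rows, X.n_cols);
  for (uword c = 0; c < X.n_cols; ++c) {
    vec col = X.col(c);
    vec tr = col(train);
    double mu = mean(tr);
    double sd = stddev(tr);  // n-1
    if (sd < 1e-12) Xs.col(c).zeros();
    else Xs.col(c) = (col - mu) / sd;
  }
}

// Fit MKL on train rows and predict test rows. X is n x (nroi*ncon) with
// ROI-major column blocks. Kernels: per-ROI linear Gram on standardized
// features, trace-normalized to trace = n_train.
struct FoldResult {
  vec beta;
  vec dec;       // decision values for test rows
  bool converged;
};

static FoldResult fold_fit(const mat& X, const vec& y, const uvec& train,
                           const uvec& test, int nroi, double C, double p,
                           double tol, int max_alt, double svm_eps) {
  const int ncon = X.n_cols / nroi;
  const int ntr = train.n_elem;
  mat Xs;
  standardize_train(X, train, Xs);
  vec ytr = y(train);
  mat Xtr = Xs.rows(train);
  mat Xte = Xs.rows(test);
  vec scale(nroi, fill::ones);
  for (int m = 0; m < nroi; ++m) {
    mat A = Xtr.cols(m * ncon, (m + 1) * ncon - 1);
    double tr = accu(square(A));  // trace of A A'
    scale(m) = (tr > 1e-12) ? (double)ntr / tr : 1.0;
  }
  MklFit f = mkl_train_feat(Xtr, scale, ytr, ncon, C, p, tol, max_alt,
                            svm_eps);
  vec ay = f.alpha % ytr;
  vec dec(test.n_elem, fill::value(f.b));
  for (int m = 0; m < nroi; ++m) {
    if (f.beta(m) <= 0) continue;
    mat A = Xtr.cols(m * ncon, (m + 1) * ncon - 1);
    mat B = Xte.cols(m * ncon, (m + 1) * ncon - 1);
    dec += (f.beta(m) * scale(m)) * (B * (A.t() * ay));
  }
  FoldResult r;
  r.beta = f.beta; r.dec = dec; r.converged = f.converged;
  return r;
}

// [[Rcpp::export]]
Rcpp::List cpp_fit_predict(const arma::mat& X, const arma::vec& y,
                           const arma::uvec& train, const arma::uvec& test,
                           int nroi, double C, double p, double tol = 1e-4,
                           int max_alt = 200, double svm_eps = 1e-10) {
  FoldResult r = fold_fit(X, y, train, test, nroi, C, p, tol, max_alt, svm_eps);
  vec pred(r.dec.n_elem);
  for (uword t = 0; t < r.dec.n_elem; ++t) pred(t) = (r.dec(t) > 0) ? 1.0 : -1.0;
  return Rcpp::List::create(Rcpp::Named("decision") = r.dec,
                            Rcpp::Named("prediction") = pred,
                            Rcpp::Named("beta") = r.beta,
                            Rcpp::Named("converged") = r.converged);
}

// Generic k-fold CV: fold_id in 1..k assigns each subject to the fold in
// which it is held out. Used for the outer leave-one-pair-out loop (folds of
// size 2) and the inner stratified 10-fold loop alike.
// [[Rcpp::export]]
Rcpp::List cpp_cv(const arma::mat& X, const arma::vec& y,
                  const arma::ivec& fold_id, int nroi, double C, double p,
                  double tol = 1e-4, int max_alt = 200,
                  double svm_eps = 1e-10) {
  const int n = X.n_rows;
  const int k = fold_id.max();
  vec dec(n, fill::zeros), pred(n, fill::zeros);
  mat betas(k, nroi, fill::zeros);
  int correct = 0;
  for (int f = 1; f <= k; ++f) {
    uvec test = find(fold_id == f);
    uvec train = find(fold_id != f);
    if (test.n_elem == 0) continue;
    vec ytr = y(train);
    if (ytr.max() <= 0 || ytr.min() >= 0)
      Rcpp::stop("training fold %d contains a single class", f);
    FoldResult r = fold_fit(X, y, train, test, nroi, C, p, tol, max_alt,
                            svm_eps);
    betas.row(f - 1) = r.beta.t();
    for (uword t = 0; t < test.n_elem; ++t) {
      dec(test(t)) = r.dec(t);
      double pr = (r.dec(t) > 0) ? 1.0 : -1.0;
      pred(test(t)) = pr;
      if (pr == y(test(t))) ++correct;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("decision") = dec, Rcpp::Named("prediction") = pred,
      Rcpp::Named("beta") = betas,
      Rcpp::Named("accuracy") = (double)correct / n);
}
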