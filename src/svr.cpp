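#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// L2-regularized L1-loss (epsilon-insensitive) linear support-vector
// regression, solved by dual coordinate descent with shrinking in the
// LIBLINEAR style (Ho & Lin 2012). The intercept is handled by augmenting
// every sample with a constant bias feature (regularized intercept).
//
// Primal:  min_w 0.5 ||w||^2 + C sum_i max(0, |w.x_i - y_i| - eps)
// Dual:    min_b 0.5 b' X X' b - y' b + eps ||b||_1,  |b_i| <= C
//
// Stopping: sum of projected-gradient violations below tol times its
// first-pass value. The shuffled sweep order uses a fixed xorshift stream,
// so fits are fully deterministic.
//
// [[Rcpp::export(name = ".svr_cd_fit")]]
List svr_cd_fit(NumericMatrix X, NumericVector y, double C, double eps,
                double bias, double tol, int max_passes,
                Nullable<NumericVector> beta_init = R_NilValue) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> w(p, 0.0);
  double wb = 0.0;
  std::vector<double> beta(n, 0.0), qii(n);
  std::vector<double> Xt((size_t)n * p);   // sample-contiguous copy
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i)
      Xt[(size_t)i * p + j] = X(i, j);
  for (int i = 0; i < n; ++i) {
    const double *xi = &Xt[(size_t)i * p];
    double s = bias * bias;
    for (int j = 0; j < p; ++j) s += xi[j] * xi[j];
    qii[i] = s;
  }
  if (beta_init.isNotNull()) {
    NumericVector b0(beta_init);
    if ((int)b0.size() != n) stop("beta_init length mismatch");
    for (int i = 0; i < n; ++i) {
      double b = b0[i];
      if (b > C) b = C; else if (b < -C) b = -C;
      beta[i] = b;
      if (b != 0.0) {
        const double *xi = &Xt[(size_t)i * p];
        for (int j = 0; j < p; ++j) w[j] += b * xi[j];
        wb += b * bias;
      }
    }
  }
  std::vector<int> index(n);
  for (int i = 0; i < n; ++i) index[i] = i;
  int active = n;
  unsigned long long rng = 88172645463325252ULL;
  auto next_rand = [&rng]() {
    rng ^= rng << 13; rng ^= rng >> 7; rng ^= rng << 17;
    return rng;
  };
  double gnorm1_init = -1.0;
  double gmax_old = HUGE_VAL;
  int pass = 0;
  bool converged = false;
  for (pass = 0; pass < max_passes; ++pass) {
    double gmax_new = 0.0, gnorm1_new = 0.0;
    for (int i = active - 1; i > 0; --i) {
      int j = (int)(next_rand() % (unsigned long long)(i + 1));
      std::swap(index[i], index[j]);
    }
    for (int s = 0; s < active; ++s) {
      int i = index[s];
      if (qii[i] <= 0.0) continue;
      const double *xi = &Xt[(size_t)i * p];
      double g = wb * bias;
      for (int j = 0; j < p; ++j) g += w[j] * xi[j];
      g -= y[i];
      double gp = g + eps, gn = g - eps;
      double violation = 0.0;
      bool shrink = false;
      if (beta[i] == 0.0) {
        if (gp < 0) violation = -gp;
        else if (gn > 0) violation = gn;
        else if (gp > gmax_old && gn < -gmax_old) shrink = true;
      } else if (beta[i] >= C) {
        if (gp > 0) violation = gp;
        else if (gp < -gmax_old) shrink = true;
      } else if (beta[i] <= -C) {
        if (gn < 0) violation = -gn;
        else if (gn > gmax_old) shrink = true;
      } else if (beta[i] > 0) {
        violation = std::fabs(gp);
      } else {
        violation = std::fabs(gn);
      }
      if (shrink) {
        --active;
        std::swap(index[s], index[active]);
        --s;
        continue;
      }
      if (violation > gmax_new) gmax_new = violation;
      gnorm1_new += violation;
      double d;
      if (gp < qii[i] * beta[i]) d = -gp / qii[i];
      else if (gn > qii[i] * beta[i]) d = -gn / qii[i];
      else d = -beta[i];
      double b_new = beta[i] + d;
      if (b_new > C) b_new = C;
      else if (b_new < -C) b_new = -C;
      d = b_new - beta[i];
      if (std::fabs(d) > 1e-15) {
        beta[i] = b_new;
        for (int j = 0; j < p; ++j) w[j] += d * xi[j];
        wb += d * bias;
      }
    }
    if (gnorm1_init < 0) gnorm1_init = gnorm1_new > 0 ? gnorm1_new : 1.0;
    if (gnorm1_new <= tol * gnorm1_init) {
      if (active == n) { converged = true; ++pass; break; }
      // optimal on the active set: verify on the full set
      active = n;
      gmax_old = HUGE_VAL;
      continue;
    }
    gmax_old = gmax_new > 0 ? gmax_new : HUGE_VAL;
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["intercept"] = wb * bias,
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["passes"] = pass,
                      _["converged"] = converged);
}
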