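#include <Rcpp.h>
using namespace Rcpp;

// Soft-thresholding operator
static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// L1-penalized logistic regression path by cyclic coordinate descent on
// the IRLS quadratic approximation. Minimizes
//   -(1/n) loglik(beta0, beta) + lambda * ||beta||_1
// with an unpenalized intercept. Lambdas are expected in decreasing
// order; solutions are warm-started along the path. Returns a
// (p+1) x nlambda matrix whose first row is the intercept.
// [[Rcpp::export(name = ".lasso_cd_path")]]
NumericMatrix lasso_cd_path(NumericMatrix X, NumericVector y,
                            NumericVector lambda,
                            double tol = 1e-9, int maxit = 100000) {
  const int n = X.nrow(), p = X.ncol(), nl = lambda.size();
  NumericMatrix out(p + 1, nl);
  std::vector<double> beta(p, 0.0);
  double ybar = mean(y);
  double beta0 = std::log(ybar / (1.0 - ybar));
  std::vector<double> eta(n), w(n), z(n), r(n), eta_old(n);
  for (int i = 0; i < n; ++i) eta[i] = beta0;

  for (int l = 0; l < nl; ++l) {
    double lam = lambda[l];
    for (int outer = 0; outer < 100; ++outer) {
      eta_old = eta;
      // IRLS working response at current eta
      for (int i = 0; i < n; ++i) {
        double pi = 1.0 / (1.0 + std::exp(-eta[i]));
        if (pi < 1e-8) pi = 1e-8;
        if (pi > 1.0 - 1e-8) pi = 1.0 - 1e-8;
        double wi = pi * (1.0 - pi);
        if (wi < 1e-6) wi = 1e-6;
        w[i] = wi;
        z[i] = eta[i] + (y[i] - pi) / wi;
        r[i] = z[i] - eta[i];
      }
      // inner CD on the weighted least-squares problem
      for (int it = 0; it < maxit; ++it) {
        double max_change = 0.0;
        // intercept (unpenalized)
        double sw = 0.0, swr = 0.0;
        for (int i = 0; i < n; ++i) { sw += w[i]; swr += w[i] * r[i]; }
        double d0 = swr / sw;
        if (std::fabs(d0) > max_change) max_change = std::fabs(d0);
        beta0 += d0;
        for (int i = 0; i < n; ++i) r[i] -= d0;
        for (int j = 0; j < p; ++j) {
          double num = 0.0, den = 0.0;
          for (int i = 0; i < n; ++i) {
            double xij = X(i, j);
            num += w[i] * xij * r[i];
            den += w[i] * xij * xij;
          }
          if (den <= 0.0) continue;
          double rho = num / n + (den / n) * beta[j];
          double bnew = soft(rho, lam) / (den / n);
          double diff = bnew - beta[j];
          if (diff != 0.0) {
            for (int i = 0; i < n; ++i) r[i] -= X(i, j) * diff;
            beta[j] = bnew;
            if (std::fabs(diff) > max_change) max_change = std::fabs(diff);
          }
        }
        if (max_change < tol) break;
      }
      // new linear predictor; stop when IRLS has stabilized
      double eta_change = 0.0;
      for (int i = 0; i < n; ++i) {
        eta[i] = z[i] - r[i];
        double d = std::fabs(eta[i] - eta_old[i]);
        if (d > eta_change) eta_change = d;
      }
      if (eta_change < 1e-8) break;
    }
    out(0, l) = beta0;
    for (int j = 0; j < p; ++j) out(j + 1, l) = beta[j];
  }
  return out;
}
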