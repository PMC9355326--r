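#include <Rcpp.h>
using namespace Rcpp;

inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent for ||y - X b||^2 + lambda * sum |b_j|,
// in covariance form: works entirely from X'X and X'y.
// [[Rcpp::export(name = ".cd_sweeps")]]
List cd_sweeps(NumericMatrix XtX, NumericVector Xty, NumericVector beta0,
               double lambda, double tol, int max_sweeps) {
  int p = Xty.size();
  NumericVector beta = clone(beta0);
  // grad_part[j] = X_j' (y - X beta) + xtx_j * beta_j, maintained incrementally
  std::vector<double> xb(p);  // (XtX %*% beta)_j
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int k = 0; k < p; ++k) s += XtX(j, k) * beta[k];
    xb[j] = s;
  }
  int it = 0;
  bool converged = false;
  while (it < max_sweeps) {
    ++it;
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      double xtxj = XtX(j, j);
      double z = Xty[j] - xb[j] + xtxj * beta[j];
      double bj = soft_threshold(z, lambda / 2.0) / xtxj;
      double d = bj - beta[j];
      if (d != 0.0) {
        for (int k = 0; k < p; ++k) xb[k] += XtX(k, j) * d;
        if (std::fabs(d) > delta) delta = std::fabs(d);
        beta[j] = bj;
      }
    }
    if (delta < tol) { converged = true; break; }
  }
  return List::create(_["beta"] = beta, _["iterations"] = it,
                      _["converged"] = converged);
}
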