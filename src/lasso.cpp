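#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent on f(b) = ||Xb - y||^2 + lambda * ||b||_1,
// parameterised by the Gram matrix XtX = X'X and Xty = X'y so that a cohort
// fit can share one Gram factorisation across all n column problems.
// Convergence: max coordinate update below tol. No intercept, no
// standardisation; lambda = 0 reduces to least squares.
// [[Rcpp::export]]
List lassoCoordinateDescent(const NumericMatrix& XtX,
                            const NumericVector& Xty,
                            double lambda,
                            double tol,
                            int maxIter,
                            const NumericVector& init) {
  const int p = XtX.ncol();
  NumericVector b = clone(init);
  // g = XtX %*% b, maintained incrementally
  std::vector<double> g(p, 0.0);
  for (int k = 0; k < p; ++k) {
    if (b[k] != 0.0) {
      for (int j = 0; j < p; ++j) g[j] += XtX(j, k) * b[k];
    }
  }
  const double thr = lambda / 2.0;
  double maxDelta = R_PosInf;
  int iter = 0;
  bool converged = false;
  for (iter = 0; iter < maxIter; ++iter) {
    maxDelta = 0.0;
    for (int k = 0; k < p; ++k) {
      const double akk = XtX(k, k);
      if (akk <= 0.0) { // identically-zero column: coefficient stays 0
        if (b[k] != 0.0) {
          for (int j = 0; j < p; ++j) g[j] -= XtX(j, k) * b[k];
          b[k] = 0.0;
        }
        continue;
      }
      const double rho = Xty[k] - g[k] + akk * b[k];
      double bk;
      if (rho > thr)       bk = (rho - thr) / akk;
      else if (rho < -thr) bk = (rho + thr) / akk;
      else                 bk = 0.0;
      const double delta = bk - b[k];
      if (delta != 0.0) {
        for (int j = 0; j < p; ++j) g[j] += XtX(j, k) * delta;
        b[k] = bk;
        const double ad = std::abs(delta);
        if (ad > maxDelta) maxDelta = ad;
      }
    }
    if (maxDelta < tol) { converged = true; ++iter; break; }
  }
  return List::create(_["coef"] = b,
                      _["converged"] = converged,
                      _["iterations"] = iter,
                      _["maxDelta"] = maxDelta);
}
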