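#include <Rcpp.h>
using namespace Rcpp;

// Transfer function H(x) = (a x - b) / (1 - exp(-d (a x - b))) with the
// removable singularity at a x = b expanded analytically:
// u/(1-exp(-d u)) = 1/d + u/2 + d u^2/12 + O(u^4).
static inline double transferRate(double x, double a, double b, double d) {
  const double u = a * x - b;
  const double du = d * u;
  if (std::abs(du) < 1e-8) {
    return 1.0 / d + u / 2.0 + d * u * u / 12.0;
  }
  if (du < -700.0) return 0.0; // exp overflow guard; limit is 0
  return u / (1.0 - std::exp(-du));
}

// [[Rcpp::export]]
NumericVector firingRateCpp(const NumericVector& x, double a, double b,
                            double d) {
  const int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = transferRate(x[i], a, b, d);
  return out;
}

// Euler-Maruyama integration of the reduced dynamic mean field model:
//   dS_i = [-S_i/tauS + (1 - S_i) gam H(x_i)] dt + sigma sqrt(dt) dW_i
//   x_i  = w JN S_i + G JN sum_j C_ij S_j + I0
// S is clipped to [0,1] after every step. Noise is drawn from R's RNG so a
// set.seed() call in R makes the trajectory bit-reproducible.
// Returns the trajectory at dt resolution, (nSteps+1) x n, row 1 = S0.
// [[Rcpp::export]]
List dmfIntegrateCpp(const NumericMatrix& C, double a, double b, double d,
                     double gam, double tauS, double w, double JN, double I0,
                     double G, double sigma, double dt, int nSteps,
                     const NumericVector& S0) {
  const int n = C.ncol();
  NumericMatrix S(nSteps + 1, n);
  std::vector<double> s(n), coup(n);
  for (int i = 0; i < n; ++i) { s[i] = S0[i]; S(0, i) = s[i]; }
  const double sqdt = std::sqrt(dt);
  RNGScope scope;
  for (int t = 0; t < nSteps; ++t) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += C(i, j) * s[j];
      coup[i] = acc;
    }
    for (int i = 0; i < n; ++i) {
      const double x = w * JN * s[i] + G * JN * coup[i] + I0;
      const double drift = -s[i] / tauS + (1.0 - s[i]) * gam * transferRate(x, a, b, d);
      double snew = s[i] + dt * drift;
      if (sigma > 0.0) snew += sigma * sqdt * R::norm_rand();
      if (snew < 0.0) snew = 0.0;
      if (snew > 1.0) snew = 1.0;
      if (!std::isfinite(snew)) {
        return List::create(_["trajectory"] = S, _["ok"] = false,
                            _["badStep"] = t + 1, _["badNode"] = i + 1);
      }
      s[i] = snew;
      S(t + 1, i) = snew;
    }
  }
  return List::create(_["trajectory"] = S, _["ok"] = true,
                      _["badStep"] = -1, _["badNode"] = -1);
}

// Balloon-Windkessel hemodynamic forward model, driven by the synaptic
// gating trajectory (one column per region), integrated by Euler at the same
// dt. State per region: vasodilatory signal sv, inflow f, volume v,
// deoxyhemoglobin q. BOLD = V0 (k1(1-q) + k2(1 - q/v) + k3(1 - v)).
// [[Rcpp::export]]
NumericMatrix boldForwardCpp(const NumericMatrix& S, double dt, double kappa,
                             double gammaH, double tauH, double alpha,
                             double rho, double V0) {
  const int T = S.nrow(), n = S.ncol();
  NumericMatrix bold(T, n);
  const double k1 = 7.0 * rho, k2 = 2.0, k3 = 2.0 * rho - 0.2;
  const double ia = 1.0 / alpha;
  for (int i = 0; i < n; ++i) {
    double sv = 0.0, f = 1.0, v = 1.0, q = 1.0;
    for (int t = 0; t < T; ++t) {
      const double z = S(t, i);
      const double fv = std::pow(v, ia);          // outflow
      const double E = 1.0 - std::pow(1.0 - rho, 1.0 / f); // O2 extraction
      const double dsv = z - kappa * sv - gammaH * (f - 1.0);
      const double df = sv;
      const double dv = (f - fv) / tauH;
      const double dq = (f * E / rho - fv * q / v) / tauH;
      sv += dt * dsv;
      f += dt * df;
      if (f < 1e-6) f = 1e-6;
      v += dt * dv;
      if (v < 1e-6) v = 1e-6;
      q += dt * dq;
      if (q < 1e-6) q = 1e-6;
      bold(t, i) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) + k3 * (1.0 - v));
    }
  }
  return bold;
}
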