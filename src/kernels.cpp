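// Hot loops of the point-cloud likelihood: the M x K Gaussian-mixture sums
// dominate Gibbs sweeps (local Metropolis, HMC gradients) and the global
// rotation scans over thousands of grid quaternions.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// log-likelihood sum_m log[(1/K) sum_k phi2(y_m; c_k, s2)] with the
// per-point log density floored (underflow guard)
// [[Rcpp::export]]
double cpp_cloud_loglik(const NumericMatrix& y, const NumericMatrix& ctr,
                        double s2, double log_floor) {
  const int M = y.nrow(), K = ctr.nrow();
  const double lnorm = std::log(2.0 * M_PI * s2) + std::log((double)K);
  const double inv2 = 1.0 / (2.0 * s2);
  double ll = 0.0;
  for (int m = 0; m < M; ++m) {
    double s = 0.0;
    const double ym0 = y(m, 0), ym1 = y(m, 1);
    for (int k = 0; k < K; ++k) {
      const double dx = ym0 - ctr(k, 0), dy = ym1 - ctr(k, 1);
      s += std::exp(-(dx * dx + dy * dy) * inv2);
    }
    double lp = (s > 0.0) ? std::log(s) - lnorm : R_NegInf;
    ll += (lp < log_floor) ? log_floor : lp;
  }
  return ll;
}

// gradient of the same log-likelihood with respect to the projected centers:
// d ll / d c_k = sum_m resp_mk (y_m - c_k) / s2
// [[Rcpp::export]]
NumericMatrix cpp_cloud_grad_centers(const NumericMatrix& y,
                                     const NumericMatrix& ctr, double s2) {
  const int M = y.nrow(), K = ctr.nrow();
  const double inv2 = 1.0 / (2.0 * s2);
  NumericMatrix grad(K, 2);
  std::vector<double> w(K);
  for (int m = 0; m < M; ++m) {
    double s = 0.0;
    const double ym0 = y(m, 0), ym1 = y(m, 1);
    for (int k = 0; k < K; ++k) {
      const double dx = ym0 - ctr(k, 0), dy = ym1 - ctr(k, 1);
      w[k] = std::exp(-(dx * dx + dy * dy) * inv2);
      s += w[k];
    }
    if (s <= 0.0) continue;
    for (int k = 0; k < K; ++k) {
      const double r = w[k] / s;
      grad(k, 0) += r * (ym0 - ctr(k, 0)) / s2;
      grad(k, 1) += r * (ym1 - ctr(k, 1)) / s2;
    }
  }
  return grad;
}

// rotation-scan log-likelihoods: one value per grid rotation g, centers
// given as G x K matrices of projected x and y coordinates
// [[Rcpp::export]]
NumericVector cpp_scan_loglik(const NumericMatrix& y, const NumericMatrix& cx,
                              const NumericMatrix& cy, double s2,
                              double log_floor) {
  const int M = y.nrow(), G = cx.nrow(), K = cx.ncol();
  const double lnorm = std::log(2.0 * M_PI * s2) + std::log((double)K);
  const double inv2 = 1.0 / (2.0 * s2);
  NumericVector out(G);
  for (int g = 0; g < G; ++g) {
    double ll = 0.0;
    for (int m = 0; m < M; ++m) {
      double s = 0.0;
      const double ym0 = y(m, 0), ym1 = y(m, 1);
      for (int k = 0; k < K; ++k) {
        const double dx = ym0 - cx(g, k), dy = ym1 - cy(g, k);
        s += std::exp(-(dx * dx + dy * dy) * inv2);
      }
      double lp = (s > 0.0) ? std::log(s) - lnorm : R_NegInf;
      ll += (lp < log_floor) ? log_floor : lp;
    }
    out[g] = ll;
  }
  return out;
}
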