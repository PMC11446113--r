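#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Best log-likelihood over restarts of a 1-D k-component Gaussian mixture
// fitted by EM. Initial means for each restart are supplied (drawn by the
// caller under its RNG); variances start at var(x) and are floored.
// [[Rcpp::export]]
double gmm_best_loglik_cpp(NumericVector x, NumericMatrix mu0,
                           double floor_var, double tol, int max_iter) {
  const int n = x.size();
  const int k = mu0.ncol();
  const int restarts = mu0.nrow();
  double xm = 0.0, xv = 0.0;
  for (int i = 0; i < n; ++i) xm += x[i];
  xm /= n;
  for (int i = 0; i < n; ++i) xv += (x[i] - xm) * (x[i] - xm);
  xv /= n;
  const double LOG2PI = std::log(2.0 * M_PI);
  double best = R_NegInf;
  std::vector<double> mu(k), v(k), w(k), nk(k), sum1(k), sum2(k);
  std::vector<double> logd(k);
  std::vector<std::vector<double> > resp(k, std::vector<double>(n));
  for (int r = 0; r < restarts; ++r) {
    for (int j = 0; j < k; ++j) {
      mu[j] = mu0(r, j);
      v[j] = std::max(xv, floor_var);
      w[j] = 1.0 / k;
    }
    double ll_old = R_NegInf, ll = R_NegInf;
    for (int it = 0; it < max_iter; ++it) {
      ll = 0.0;
      for (int j = 0; j < k; ++j) { nk[j] = 0; sum1[j] = 0; sum2[j] = 0; }
      for (int i = 0; i < n; ++i) {
        double m = R_NegInf;
        for (int j = 0; j < k; ++j) {
          double z = x[i] - mu[j];
          logd[j] = std::log(w[j]) -
            0.5 * (LOG2PI + std::log(v[j]) + z * z / v[j]);
          if (logd[j] > m) m = logd[j];
        }
        double s = 0.0;
        for (int j = 0; j < k; ++j) s += std::exp(logd[j] - m);
        double lse = m + std::log(s);
        ll += lse;
        for (int j = 0; j < k; ++j) {
          double rij = std::exp(logd[j] - lse);
          resp[j][i] = rij;
          nk[j] += rij;
          sum1[j] += rij * x[i];
        }
      }
      bool dead = false;
      for (int j = 0; j < k; ++j) if (nk[j] < 1e-10) dead = true;
      if (dead) break;
      for (int j = 0; j < k; ++j) {
        w[j] = nk[j] / n;
        mu[j] = sum1[j] / nk[j];
      }
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < k; ++j) {
          double z = x[i] - mu[j];
          sum2[j] += resp[j][i] * z * z;
        }
      for (int j = 0; j < k; ++j)
        v[j] = std::max(sum2[j] / nk[j], floor_var);
      if (R_FINITE(ll_old) && ll - ll_old < tol) break;
      ll_old = ll;
    }
    if (R_FINITE(ll) && ll > best) best = ll;
  }
  return best;
}
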