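#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cyclic coordinate descent for min_b ||y - X b||^2 + lambda1 ||b||_1.
// Loss carries no 1/(2n) factor, so each update soft-thresholds at
// lambda1 / 2:  b_j <- S(x_j' r_(-j), lambda1/2) / ||x_j||^2.
// Residuals are updated incrementally; one sweep costs O(np).
// [[Rcpp::export]]
List cdLassoCpp(const NumericMatrix& X, const NumericVector& y,
                double lambda1, double tol, int maxSweeps,
                const NumericVector& beta0) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector beta = clone(beta0);
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i];
  for (int j = 0; j < p; ++j) {
    const double bj = beta[j];
    if (bj != 0.0)
      for (int i = 0; i < n; ++i) r[i] -= X(i, j) * bj;
  }
  std::vector<double> nrm2(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    nrm2[j] = s;
  }
  const double thr = lambda1 / 2.0;
  std::vector<double> objPath;
  objPath.reserve(64);
  bool converged = false;
  int sweeps = 0;
  while (sweeps < maxSweeps) {
    double maxDelta = 0.0;
    for (int j = 0; j < p; ++j) {
      if (nrm2[j] <= 0.0) { beta[j] = 0.0; continue; }
      double z = nrm2[j] * beta[j];
      for (int i = 0; i < n; ++i) z += X(i, j) * r[i];
      double bnew = 0.0;
      if (z > thr) bnew = (z - thr) / nrm2[j];
      else if (z < -thr) bnew = (z + thr) / nrm2[j];
      const double d = beta[j] - bnew;
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] += X(i, j) * d;
        beta[j] = bnew;
      }
      const double ad = std::fabs(d);
      if (ad > maxDelta) maxDelta = ad;
    }
    ++sweeps;
    double rss = 0.0;
    for (int i = 0; i < n; ++i) rss += r[i] * r[i];
    double l1 = 0.0;
    for (int j = 0; j < p; ++j) l1 += std::fabs(beta[j]);
    objPath.push_back(rss + lambda1 * l1);
    if (maxDelta < tol) { converged = true; break; }
  }
  return List::create(_["beta"] = beta,
                      _["nSweeps"] = sweeps,
                      _["converged"] = converged,
                      _["objectivePath"] = NumericVector(objPath.begin(),
                                                         objPath.end()));
}
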