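#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dual coordinate descent for epsilon-insensitive RBF SVR with the bias
// absorbed into the kernel (Q = K + 1) and per-sample box constraints:
//
//   min_beta 1/2 beta' Q beta - y' beta + eps * ||beta||_1
//   s.t. |beta_i| <= C_i
//
// Each coordinate has a closed-form soft-thresholded, box-clipped update.
// The gradient vector Q beta is maintained incrementally.
// [[Rcpp::export]]
NumericVector svr_cd_fit(NumericMatrix Q, NumericVector y,
                         NumericVector Cvec, double eps,
                         double tol, int maxSweeps,
                         NumericVector betaInit) {
  const int n = y.size();
  NumericVector beta = clone(betaInit);
  std::vector<double> Qb(n, 0.0);
  for (int j = 0; j < n; ++j) {
    const double bj = beta[j];
    if (bj != 0.0) {
      const double *qj = &Q(0, j);
      for (int i = 0; i < n; ++i) Qb[i] += qj[i] * bj;
    }
  }
  for (int s = 0; s < maxSweeps; ++s) {
    double maxDelta = 0.0;
    for (int i = 0; i < n; ++i) {
      const double Ci = Cvec[i];
      const double bi = beta[i];
      const double *qi = &Q(0, i);
      if (Ci <= 0.0) {
        if (bi != 0.0) {
          for (int r = 0; r < n; ++r) Qb[r] -= qi[r] * bi;
          beta[i] = 0.0;
        }
        continue;
      }
      const double qii = qi[i];
      const double z = y[i] - (Qb[i] - qii * bi);
      double bnew = 0.0;
      if (z > eps) bnew = (z - eps) / qii;
      else if (z < -eps) bnew = (z + eps) / qii;
      if (bnew > Ci) bnew = Ci;
      else if (bnew < -Ci) bnew = -Ci;
      const double d = bnew - bi;
      if (d != 0.0) {
        beta[i] = bnew;
        for (int r = 0; r < n; ++r) Qb[r] += qi[r] * d;
        const double ad = std::fabs(d);
        if (ad > maxDelta) maxDelta = ad;
      }
    }
    if (maxDelta < tol) break;
  }
  return beta;
}
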