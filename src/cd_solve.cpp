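// Penalized weighted least-squares solver for one class block of the
// multinomial lasso: cyclic coordinate descent with soft-thresholding and
// an active-set strategy. Z is standardized (mean 0, mean square 1 per
// column); rr is the working residual z - b0 - Z b at entry; hj holds the
// per-feature curvatures mean(w * z_j^2).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".cd_solve_class")]]
List cd_solve_class(NumericMatrix Z, NumericVector w, NumericVector rr_in,
                    NumericVector b_in, double b0_in, NumericVector hj,
                    double lambda, double tol, int max_pass) {
  const int n = Z.nrow(), J = Z.ncol();
  std::vector<double> b(b_in.begin(), b_in.end());
  std::vector<double> rr(rr_in.begin(), rr_in.end());
  double b0 = b0_in;
  double sw = 0.0;
  for (int i = 0; i < n; ++i) sw += w[i];
  sw /= n;

  std::vector<int> allj(J);
  for (int j = 0; j < J; ++j) allj[j] = j;

  auto sweep_once = [&](const std::vector<int>& js) -> double {
    double ch = 0.0;
    double num = 0.0;
    for (int i = 0; i < n; ++i) num += w[i] * rr[i];
    double upd = num / (sw * n);
    b0 += upd;
    for (int i = 0; i < n; ++i) rr[i] -= upd;
    ch = std::fabs(upd);
    for (size_t idx = 0; idx < js.size(); ++idx) {
      int j = js[idx];
      const double* zj = &Z(0, j);
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += w[i] * zj[i] * rr[i];
      g = g / n + hj[j] * b[j];
      double bn = 0.0;
      double a = std::fabs(g) - lambda;
      if (a > 0.0) bn = (g > 0.0 ? a : -a) / hj[j];
      double dj = bn - b[j];
      if (dj != 0.0) {
        for (int i = 0; i < n; ++i) rr[i] -= zj[i] * dj;
        b[j] = bn;
        double adj = std::fabs(dj);
        if (adj > ch) ch = adj;
      }
    }
    return ch;
  };

  for (int pass = 0; pass < max_pass; ++pass) {
    double ch = sweep_once(allj);
    if (ch < tol) break;
    for (;;) {
      std::vector<int> act;
      act.reserve(J);
      for (int j = 0; j < J; ++j) if (b[j] != 0.0) act.push_back(j);
      if (act.empty()) break;
      double ch2 = sweep_once(act);
      if (ch2 < tol) break;
    }
  }
  return List::create(_["b"] = NumericVector(b.begin(), b.end()),
                      _["b0"] = b0);
}
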