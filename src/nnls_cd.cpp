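#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate-descent solver for nonnegative least squares on the
// normal equations: minimize 0.5 w'(AtA)w - Atb'w subject to w >= 0.
// The gradient g = AtA w - Atb is maintained incrementally; each coordinate
// update is the exact 1D minimizer clipped at zero, so the objective is
// nonincreasing. Convergence is declared when the largest projected-gradient
// component falls below tol * max|Atb|.
// [[Rcpp::export]]
List nnls_cd_cpp(NumericMatrix AtA, NumericVector Atb, NumericVector w0,
                 int max_sweeps, double tol) {
  const int n = Atb.size();
  NumericVector w = clone(w0);
  std::vector<double> g(n);
  // g = AtA w - Atb
  for (int i = 0; i < n; ++i) {
    double acc = -Atb[i];
    const double* col = &AtA(0, i);  // symmetric: row i == column i
    for (int j = 0; j < n; ++j) acc += col[j] * w[j];
    g[i] = acc;
  }
  double gscale = 0.0;
  for (int i = 0; i < n; ++i) gscale = std::max(gscale, std::fabs(Atb[i]));
  if (gscale <= 0.0) gscale = 1.0;

  bool converged = false;
  int sweep = 0;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    for (int j = 0; j < n; ++j) {
      const double d = AtA(j, j);
      if (d <= 0.0) continue;
      double wj = w[j] - g[j] / d;
      if (wj < 0.0) wj = 0.0;
      const double delta = wj - w[j];
      if (delta != 0.0) {
        const double* col = &AtA(0, j);
        for (int i = 0; i < n; ++i) g[i] += delta * col[i];
        w[j] = wj;
      }
    }
    double viol = 0.0;
    for (int i = 0; i < n; ++i) {
      const double pg = (w[i] > 0.0) ? g[i] : std::min(g[i], 0.0);
      viol = std::max(viol, std::fabs(pg));
    }
    if (viol < tol * gscale) {
      converged = true;
      ++sweep;
      break;
    }
  }
  return List::create(_["weights"] = w, _["sweeps"] = sweep,
                      _["converged"] = converged);
}
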