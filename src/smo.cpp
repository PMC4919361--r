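#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin SVM dual
//   min_a 0.5 a' Q a - e' a,  Q_ij = y_i y_j K_ij,
//   s.t. y' a = 0, 0 <= a_i <= C,
// with maximal-violating-pair working-set selection. Pairwise updates keep
// y' a = 0 exact to rounding, so the equality constraint never drifts.
// alpha0 allows warm starts (any feasible point, e.g. the solution at a
// nearby kernel during multiple-kernel weight search).
// [[Rcpp::export]]
List smo_solve(const NumericMatrix& K, const NumericVector& y, double C,
               double tol, int max_iter, const NumericVector& alpha0) {
  const int n = K.nrow();
  std::vector<double> alpha(alpha0.begin(), alpha0.end());
  std::vector<double> G(n);  // gradient of the minimised form: Q a - e

  for (int i = 0; i < n; ++i) {
    double s = -1.0;
    for (int j = 0; j < n; ++j)
      if (alpha[j] != 0.0) s += y[i] * y[j] * K(i, j) * alpha[j];
    G[i] = s;
  }

  int iter = 0;
  double gmax = 0.0, gmin = 0.0;
  bool converged = false;
  // variables within eps_b of a box bound are treated as bounded during
  // working-set selection, so a numerically-tiny free alpha can never be
  // chosen for a step that immediately clips to zero (a stall)
  const double eps_b = 1e-12 * C;
  for (; iter < max_iter; ++iter) {
    gmax = -std::numeric_limits<double>::infinity();
    gmin = std::numeric_limits<double>::infinity();
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] > 0) ? (alpha[t] < C - eps_b) : (alpha[t] > eps_b);
      const bool low = (y[t] > 0) ? (alpha[t] > eps_b) : (alpha[t] < C - eps_b);
      if (up && v > gmax) { gmax = v; i = t; }
      if (low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) { converged = true; break; }

    const double s = y[i] * y[j];
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta <= 1e-12) eta = 1e-12;
    const double Ei = y[i] * G[i], Ej = y[j] * G[j];
    double aj = alpha[j] + y[j] * (Ei - Ej) / eta;
    double L, H;
    if (s < 0) {
      L = std::max(0.0, alpha[j] - alpha[i]);
      H = std::min(C, C + alpha[j] - alpha[i]);
    } else {
      L = std::max(0.0, alpha[i] + alpha[j] - C);
      H = std::min(C, alpha[i] + alpha[j]);
    }
    if (aj < L) aj = L;
    if (aj > H) aj = H;
    const double dj = aj - alpha[j];
    if (dj == 0.0) break;  // cannot make progress; reported as non-converged
    const double di = -s * dj;
    alpha[i] += di;
    alpha[j] += dj;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * di + y[j] * K(t, j) * dj);
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["grad"] = NumericVector(G.begin(), G.end()),
                      _["iterations"] = iter,
                      _["converged"] = converged,
                      _["kkt_violation"] = gmax - gmin);
}
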