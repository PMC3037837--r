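#include <Rcpp.h>
using namespace Rcpp;

// Soft-margin linear/kernel SVM dual solver (SMO with maximal-violating-pair
// working-set selection).  Solves
//   min_a  1/2 a' Q a - e' a   s.t.  0 <= a_i <= C,  sum_i y_i a_i = 0
// with Q_ij = y_i y_j K_ij.  Pairwise updates keep the equality constraint
// satisfied exactly (up to floating point), which the package's KKT checks
// rely on.  Deterministic for fixed inputs.
//
// Returns alpha, bias b, number of iterations, and the final KKT gap.

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(const NumericMatrix& K, const NumericVector& y, double C,
               double eps = 1e-8, int max_iter = 1000000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n)
    stop("K must be square and match length(y)");
  const double TAU = 1e-12;

  std::vector<double> alpha(n, 0.0), G(n, -1.0);  // G = grad(1/2 a'Qa - e'a)
  int iter = 0;
  double gap = R_PosInf;

  for (iter = 0; iter < max_iter; ++iter) {
    // maximal violating pair: i in I_up maximizing -y G, j in I_low minimizing
    int i = -1, j = -1;
    double Gmax = -R_PosInf, Gmin = R_PosInf;
    for (int t = 0; t < n; ++t) {
      bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    gap = Gmax - Gmin;
    if (i == -1 || j == -1 || gap < eps) break;

    double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double di = y[i] * (alpha[i] - ai_old), dj = y[j] * (alpha[j] - aj_old);
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (K(t, i) * di + K(t, j) * dj);
  }

  // bias from free support vectors (KKT); fall back to the violating-pair
  // midpoint when no alpha is strictly inside (0, C)
  double bsum = 0.0; int bcnt = 0;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 0 && alpha[t] < C) { bsum += -y[t] * G[t]; ++bcnt; }
  double b;
  if (bcnt > 0) {
    b = bsum / bcnt;
  } else {
    double Gmax = -R_PosInf, Gmin = R_PosInf;
    for (int t = 0; t < n; ++t) {
      bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > Gmax) Gmax = v;
      if (low && v < Gmin) Gmin = v;
    }
    b = (Gmax + Gmin) / 2.0;
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter, _["kkt_gap"] = gap,
                      _["converged"] = (gap < eps));
}
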