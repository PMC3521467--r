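// Sequential minimal optimization for binary C-SVC on a precomputed
// kernel.  Working-set selection is the maximal violating pair; the
// two-variable update and box clipping follow the standard dual solver.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List smo_train(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-3, int max_updates = 1000000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n)
    stop("kernel must be square and match y");
  std::vector<double> alpha(n, 0.0), G(n, -1.0);  // G = Q alpha - e
  const double TAU = 1e-12;

  int updates = 0;
  double m = 0.0, M = 0.0;
  while (updates < max_updates) {
    // maximal violating pair
    int i = -1, j = -1;
    m = -1e300; M = 1e300;
    for (int t = 0; t < n; ++t) {
      bool up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      double v = -y[t] * G[t];
      if (up  && v > m) { m = v; i = t; }
      if (low && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < tol) break;

    double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) + 2.0 * K(i, j);
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

    double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    if (dai == 0.0 && daj == 0.0) break;  // numerically stuck
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * y[i] * K(t, i) * dai + y[t] * y[j] * K(t, j) * daj;
    ++updates;
  }

  // rho: mean of y_t * G_t over free support vectors, else midpoint bound
  double rho;
  int nfree = 0; double sumfree = 0.0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > TAU && alpha[t] < C - TAU) {
      sumfree += y[t] * G[t];
      ++nfree;
    }
  }
  if (nfree > 0) rho = sumfree / nfree; else rho = -(m + M) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = -rho,
                      _["updates"] = updates);
}
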