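#include <Rcpp.h>
using namespace Rcpp;

// Binary C-SVC dual solver: sequential minimal optimization with
// first-order (maximal violating pair) working-set selection, as in
// standard SMO implementations. K is the precomputed kernel matrix,
// y in {-1, +1}.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, IntegerVector y, double C,
               double eps = 1e-3, int max_iter = 100000) {
  int n = K.nrow();
  std::vector<double> alpha(n, 0.0), G(n, 0.0); // G = (Q alpha)_i, Q = yy'K
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // select maximal violating pair
    double m_up = -R_PosInf, m_low = R_PosInf;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool low = (y[t] == -1 && alpha[t] < C) || (y[t] == 1 && alpha[t] > 0);
      double v = y[t] * (1.0 - G[t]); // -y * grad, grad = (Q alpha)_t - 1
      if (up && v > m_up) { m_up = v; i = t; }
      if (low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < eps) break;
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = 1e-12;
    double t_step = (m_up - m_low) / quad;
    // box limits along the feasible direction (dalpha_i = y_i t, dalpha_j = -y_j t)
    double tmax = t_step;
    tmax = std::min(tmax, y[i] > 0 ? C - alpha[i] : alpha[i]);
    tmax = std::min(tmax, y[j] > 0 ? alpha[j] : C - alpha[j]);
    if (tmax <= 0) break;
    double t_clipped = std::min(t_step, tmax);
    alpha[i] += y[i] * t_clipped;
    alpha[j] -= y[j] * t_clipped;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * t_clipped * (K(t, i) - K(t, j));
  }
  // bias from free support vectors, midpoint fallback
  double b = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 && alpha[t] < C - 1e-8) {
      double s = 0.0;
      for (int u = 0; u < n; ++u) s += alpha[u] * y[u] * K(t, u);
      b += y[t] - s;
      ++nfree;
    }
  }
  if (nfree > 0) {
    b /= nfree;
  } else {
    double m_up = -R_PosInf, m_low = R_PosInf;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool low = (y[t] == -1 && alpha[t] < C) || (y[t] == 1 && alpha[t] > 0);
      double v = -y[t] * G[t];
      if (up && v > m_up) m_up = v;
      if (low && v < m_low) m_low = v;
    }
    b = (m_up + m_low) / 2.0;
  }
  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter);
}
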