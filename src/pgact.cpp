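#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>
using namespace Rcpp;

// Soft-margin SVM dual solved by SMO with maximal-violating-pair working-set
// selection (the classic LIBSVM scheme).  The full kernel matrix is passed in:
// problem sizes here are at most ~1e3, so an n x n matrix is cheap and keeps
// the solver free of any kernel-specific code.
//
// Dual: min_a 1/2 a' Q a - e' a,  0 <= a_i <= C,  y' a = 0,  Q_ij = y_i y_j K_ij.
// Gradient G_i = (Q a)_i - 1 is maintained incrementally.
// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(const NumericMatrix& K, const IntegerVector& y,
               double C, double tol, int max_iter) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("label length must match kernel size");

  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0);
  int iter = 0;
  bool converged = false;

  while (iter < max_iter) {
    // working-set selection: i maximises -y_t G_t over the "up" set,
    // j minimises it over the "down" set; KKT gap is the difference.
    double Gmax = -HUGE_VAL, Gmin = HUGE_VAL;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      if ((y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0)) {
        if (v > Gmax) { Gmax = v; i = t; }
      }
      if ((y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C)) {
        if (v < Gmin) { Gmin = v; j = t; }
      }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < tol) { converged = true; break; }

    const double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) + 2.0 * K(i, j);
      if (quad <= 0) quad = 1e-12;
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
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
      if (quad <= 0) quad = 1e-12;
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
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

    const double dAi = alpha[i] - old_ai;
    const double dAj = alpha[j] - old_aj;
    if (dAi != 0.0 || dAj != 0.0) {
      for (int t = 0; t < n; ++t)
        G[t] += y[t] * (y[i] * K(t, i) * dAi + y[j] * K(t, j) * dAj);
    }
    ++iter;
  }

  // rho such that the decision value is sum_t alpha_t y_t K(x_t, x) - rho,
  // averaged over free support vectors (midpoint of the KKT bounds otherwise).
  double ub = HUGE_VAL, lb = -HUGE_VAL, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];
    if (alpha[t] >= C) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 0) {
      if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      sum_free += yG;
      ++n_free;
    }
  }
  const double rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho,
                      _["iterations"] = iter,
                      _["converged"] = converged);
}

// Best-offset ungapped identity between two sequences: the shorter sequence is
// slid along the longer one without gaps; identity is the maximal number of
// matching positions divided by the shorter length (CD-HIT's denominator).
// [[Rcpp::export(name = ".ungapped_identity")]]
double ungapped_identity(const std::string& a, const std::string& b) {
  const std::string& s = a.size() <= b.size() ? a : b;
  const std::string& l = a.size() <= b.size() ? b : a;
  const int ns = (int)s.size(), nl = (int)l.size();
  if (ns == 0) stop("empty sequence");
  int best = 0;
  for (int off = 0; off + ns <= nl; ++off) {
    int m = 0;
    for (int p = 0; p < ns; ++p)
      if (s[p] == l[off + p]) ++m;
    if (m > best) best = m;
    if (best == ns) break;
  }
  return (double)best / (double)ns;
}
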