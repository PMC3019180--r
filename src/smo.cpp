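#include <Rcpp.h>
using namespace Rcpp;

// Soft-margin SVM dual solver on a precomputed Gram matrix.
//
// Minimizes 0.5 * a' Q a - e' a  subject to  y' a = 0, 0 <= a_i <= C,
// with Q_ij = y_i y_j K_ij, by sequential minimal optimization with
// maximal-violating-pair working-set selection.  The stopping rule is
// m(a) - M(a) < tol on the KKT violation gap.  Deterministic for fixed
// inputs: ties in the selection are broken by the lowest index.
//
// Returns alpha, the bias b (decision f = sum_i a_i y_i K(x, i) + b),
// the iteration count and a convergence flag.

static const double TAU = 1e-12;

// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-4, int max_iter = 100000) {
  int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("labels must match kernel dimension");

  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  int iter = 0;
  bool converged = false;

  while (iter < max_iter) {
    // working-set selection: maximal violating pair
    double m_up = -std::numeric_limits<double>::infinity();
    double m_low = std::numeric_limits<double>::infinity();
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool in_up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (in_up && v > m_up) { m_up = v; i = t; }
      if (in_low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < tol) { converged = true; break; }

    double old_ai = alpha[i], old_aj = alpha[j];
    double Kii = K(i, i), Kjj = K(j, j), Kij = K(i, j);

    if (y[i] != y[j]) {
      // Q_ij = y_i y_j K_ij = -K_ij here, so the pair curvature is
      // K_ii + K_jj - 2 K_ij in both branches
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
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
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
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

    double dai = y[i] * (alpha[i] - old_ai);
    double daj = y[j] * (alpha[j] - old_aj);
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (K(t, i) * dai + K(t, j) * daj);
    ++iter;
  }

  // bias: average over free support vectors, else midpoint of the bounds
  double ub = std::numeric_limits<double>::infinity();
  double lb = -std::numeric_limits<double>::infinity();
  double sum_free = 0.0;
  int nr_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] >= C - 1e-12) {
      if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-12) {
      if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++nr_free;
      sum_free += yG;
    }
  }
  double rho = nr_free > 0 ? sum_free / nr_free : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = -rho,
                      _["iterations"] = iter,
                      _["converged"] = converged);
}
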