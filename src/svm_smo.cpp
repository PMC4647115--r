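#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sequential minimal optimization for the C-SVC dual with a linear kernel.
// Solves min_a 0.5 a'Qa - e'a, 0 <= a_i <= C, y'a = 0, with Q_ij = y_i y_j K_ij,
// using maximal-violating-pair working-set selection. The bias b is the
// unpenalized Lagrange multiplier of the equality constraint (standard SVM
// convention: only w is regularized).
//
// K is passed as a dense kernel matrix over ALL rows of the data set; `idx`
// selects the training subset, so LOOCV can reuse one Gram matrix per panel.

static const double TAU = 1e-12;

struct SmoFit {
  std::vector<double> alpha;
  double b;
  int iter;
  bool converged;
};

static SmoFit smo_solve(const NumericMatrix& K, const IntegerVector& idx,
                        const NumericVector& y, double C, double tol,
                        int max_iter) {
  const int n = idx.size();
  std::vector<double> alpha(n, 0.0), G(n, -1.0), yy(n);
  for (int t = 0; t < n; ++t) yy[t] = y[idx[t]];

  int it = 0;
  bool converged = false;
  double Mup = 0.0, mlow = 0.0;
  while (it < max_iter) {
    // working-set selection: i maximizes -y*G over I_up, j minimizes over I_low
    int i = -1, j = -1;
    Mup = -HUGE_VAL; mlow = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      double v = -yy[t] * G[t];
      bool up  = (yy[t] > 0 && alpha[t] < C) || (yy[t] < 0 && alpha[t] > 0);
      bool low = (yy[t] > 0 && alpha[t] > 0) || (yy[t] < 0 && alpha[t] < C);
      if (up  && v > Mup)  { Mup = v;  i = t; }
      if (low && v < mlow) { mlow = v; j = t; }
    }
    if (i < 0 || j < 0 || Mup - mlow < tol) { converged = true; break; }

    const double Kii = K(idx[i], idx[i]), Kjj = K(idx[j], idx[j]),
                 Kij = K(idx[i], idx[j]);
    const double old_ai = alpha[i], old_aj = alpha[j];

    if (yy[i] != yy[j]) {
      double quad = Kii + Kjj - 2.0 * Kij;
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
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
        else if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
        else if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    for (int t = 0; t < n; ++t) {
      G[t] += yy[t] * (yy[i] * dai * K(idx[t], idx[i]) +
                       yy[j] * daj * K(idx[t], idx[j]));
    }
    ++it;
  }

  // bias from KKT: for free alpha, b = -y_i * G_i; else midpoint of bounds
  double bsum = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 0 && alpha[t] < C) { bsum += -yy[t] * G[t]; ++nfree; }
  }
  double b;
  if (nfree > 0) b = bsum / nfree;
  else b = -(Mup + mlow) / 2.0;

  SmoFit fit;
  fit.alpha = std::move(alpha);
  fit.b = b; fit.iter = it; fit.converged = converged;
  return fit;
}

static void weight_vector(const NumericMatrix& X, const IntegerVector& idx,
                          const NumericVector& y, const std::vector<double>& alpha,
                          double* w) {
  const int p = X.ncol(), n = idx.size();
  for (int k = 0; k < p; ++k) w[k] = 0.0;
  for (int t = 0; t < n; ++t) {
    const double coef = alpha[t] * y[idx[t]];
    if (coef == 0.0) continue;
    const int r = idx[t];
    for (int k = 0; k < p; ++k) w[k] += coef * X(r, k);
  }
}

// [[Rcpp::export]]
List cpp_svm_train(NumericMatrix X, NumericVector y, double cost,
                   double tol = 1e-6, int max_iter = 200000) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) s += X(i, k) * X(j, k);
      K(i, j) = s; K(j, i) = s;
    }
  IntegerVector idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  SmoFit fit = smo_solve(K, idx, y, cost, tol, max_iter);
  NumericVector w(p);
  weight_vector(X, idx, y, fit.alpha, REAL(w));
  return List::create(_["w"] = w, _["b"] = fit.b,
                      _["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
                      _["iterations"] = fit.iter, _["converged"] = fit.converged);
}

// Leave-one-out CV for the linear SVM: n fits on n-1 rows sharing one Gram
// matrix. Returns the held-out decision score per sample and the per-feature
// weight averaged across the n fold models (signed average).
// [[Rcpp::export]]
List cpp_svm_loocv(NumericMatrix X, NumericVector y, double cost,
                   double tol = 1e-6, int max_iter = 200000) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) s += X(i, k) * X(j, k);
      K(i, j) = s; K(j, i) = s;
    }

  NumericVector scores(n), wbar(p), wabs(p);
  std::vector<double> w(p);
  bool all_converged = true;
  IntegerVector idx(n - 1);
  for (int out = 0; out < n; ++out) {
    int t = 0;
    for (int i = 0; i < n; ++i) if (i != out) idx[t++] = i;
    SmoFit fit = smo_solve(K, idx, y, cost, tol, max_iter);
    all_converged = all_converged && fit.converged;
    weight_vector(X, idx, y, fit.alpha, w.data());
    double s = fit.b;
    for (int k = 0; k < p; ++k) {
      s += w[k] * X(out, k);
      wbar[k] += w[k] / n;
      wabs[k] += std::fabs(w[k]) / n;
    }
    scores[out] = s;
  }
  return List::create(_["scores"] = scores, _["avg_w"] = wbar,
                      _["avg_abs_w"] = wabs,
                      _["converged"] = all_converged);
}
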