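#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM,
//   min_w 0.5*||w||^2 + C * sum_i max(0, 1 - y_i * w.x_i),
// following the liblinear algorithm: random-permutation sweeps over dual
// coordinates, projected-gradient stopping, and shrinking of coordinates
// stuck at their bounds (with a final unshrunk pass before declaring
// convergence). The intercept is handled by augmenting every instance with a
// constant feature `bias`, i.e. it is (weakly) regularized. Coordinate
// shuffling draws from R's RNG, so results are reproducible under set.seed().
//
// X: n x d numeric matrix; y: labels in {-1, +1}; C: soft-margin cost.
// [[Rcpp::export]]
List dcd_linear_svm(const NumericMatrix& X, const NumericVector& y, double C,
                    double bias = 1.0, int max_iter = 2000, double tol = 0.1) {
  const int n = X.nrow(), d = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  for (int i = 0; i < n; ++i)
    if (y[i] != 1.0 && y[i] != -1.0) stop("y must be in {-1, +1}");

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> alpha(n, 0.0), w(d, 0.0), qii(n);
  double wb = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = bias * bias;
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    qii[i] = s;
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  int active = n;
  double pgmax_old = INF, pgmin_old = -INF;
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    double pgmax_new = -INF, pgmin_new = INF;
    for (int i = active - 1; i > 0; --i) {   // shuffle active coordinates
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    for (int s = 0; s < active; ++s) {
      const int i = idx[s];
      double g = wb * bias;
      for (int j = 0; j < d; ++j) g += w[j] * X(i, j);
      g = y[i] * g - 1.0;
      double pg = g;
      if (alpha[i] == 0.0) {
        if (g > pgmax_old) {            // shrink: pinned at lower bound
          --active;
          std::swap(idx[s], idx[active]);
          --s;
          continue;
        }
        if (g >= 0.0) pg = 0.0;
      } else if (alpha[i] == C) {
        if (g < pgmin_old) {            // shrink: pinned at upper bound
          --active;
          std::swap(idx[s], idx[active]);
          --s;
          continue;
        }
        if (g <= 0.0) pg = 0.0;
      }
      if (pg > pgmax_new) pgmax_new = pg;
      if (pg < pgmin_new) pgmin_new = pg;
      if (std::fabs(pg) > 1e-12) {
        double a_old = alpha[i];
        double a_new = a_old - g / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
          wb += delta * bias;
        }
      }
    }
    if (pgmax_new - pgmin_new <= tol) {
      if (active == n) { ++iter; break; }
      active = n;                        // unshrink and verify on all coords
      pgmax_old = INF;
      pgmin_old = -INF;
      continue;
    }
    pgmax_old = pgmax_new <= 0.0 ? INF : pgmax_new;
    pgmin_old = pgmin_new >= 0.0 ? -INF : pgmin_new;
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["b"] = wb * bias,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iterations"] = iter);
}
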