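// Block coordinate-descent graphical lasso (off-diagonal penalty only).
// Inner loop is plain coordinate descent on each column's lasso
// subproblem; sized for the small matrices of windowed connectivity.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".glasso_cpp")]]
List glasso_cpp(NumericMatrix s, double lambda, int max_iter, double tol) {
  const int p = s.nrow();
  NumericMatrix W(p, p), B(p, p);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j) W(i, j) = s(i, j);

  double off = 0.0;
  int n_off = 0;
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) { off += std::fabs(s(i, j)); ++n_off; }
  off = n_off ? off / n_off : 0.0;
  const double thr = tol * std::max(off, 1e-300);

  std::vector<double> beta(p - 1), s12(p - 1);
  std::vector<int> idx(p - 1);
  int it = 0;
  double change = 0.0;
  for (it = 1; it <= max_iter; ++it) {
    change = 0.0;
    int n_elem = 0;
    for (int j = 0; j < p; ++j) {
      int m = 0;
      for (int i = 0; i < p; ++i) if (i != j) idx[m++] = i;
      for (int k = 0; k < p - 1; ++k) {
        beta[k] = B(idx[k], j);
        s12[k] = s(idx[k], j);
      }
      for (int sweep = 0; sweep < 200; ++sweep) {
        double delta = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          const int rk = idx[k];
          double dot = 0.0;
          for (int l = 0; l < p - 1; ++l)
            if (l != k) dot += W(rk, idx[l]) * beta[l];
          const double r = s12[k] - dot;
          const double denom = W(rk, rk);
          double bk = 0.0;
          if (std::fabs(r) > lambda)
            bk = (r > 0 ? r - lambda : r + lambda) / denom;
          if (bk != beta[k]) {
            delta = std::max(delta, std::fabs(bk - beta[k]));
            beta[k] = bk;
          }
        }
        if (delta < 0.1 * thr) break;
      }
      for (int k = 0; k < p - 1; ++k) {
        const int i = idx[k];
        B(i, j) = beta[k];
        double w12 = 0.0;
        for (int l = 0; l < p - 1; ++l) w12 += W(i, idx[l]) * beta[l];
        change += std::fabs(W(i, j) - w12);
        ++n_elem;
        W(i, j) = w12;
        W(j, i) = w12;
      }
    }
    if (n_elem && change / n_elem < thr) break;
  }
  const bool converged = (it <= max_iter);

  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    for (int i = 0; i < p; ++i) if (i != j) dot += W(i, j) * B(i, j);
    const double t22 = 1.0 / (W(j, j) - dot);
    Theta(j, j) = t22;
    for (int i = 0; i < p; ++i) if (i != j) Theta(i, j) = -B(i, j) * t22;
  }
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      const double t = 0.5 * (Theta(i, j) + Theta(j, i));
      Theta(i, j) = t;
      Theta(j, i) = t;
      const double w = 0.5 * (W(i, j) + W(j, i));
      W(i, j) = w;
      W(j, i) = w;
    }
  return List::create(_["cov"] = W, _["precision"] = Theta,
                      _["n_iter"] = std::min(it, max_iter),
                      _["converged"] = converged);
}
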