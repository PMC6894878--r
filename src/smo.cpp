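#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-class C-SVC solved by SMO with maximal-violating-pair working-set
// selection (first order), RBF kernel. Deterministic: no randomness, fixed
// scan order, so identical inputs give identical alphas bit-for-bit.

static const double TAU = 1e-12;

struct KernelCache {
  const NumericMatrix &X;
  double gamma;
  int n, d;
  std::vector<std::vector<double> > rows;
  std::vector<char> have;
  std::vector<int> order;   // FIFO of cached row indices
  size_t max_rows;

  KernelCache(const NumericMatrix &X_, double gamma_, size_t cache_bytes)
      : X(X_), gamma(gamma_), n(X_.nrow()), d(X_.ncol()),
        rows(X_.nrow()), have(X_.nrow(), 0) {
    size_t per_row = sizeof(double) * (size_t)n;
    max_rows = cache_bytes / per_row;
    if (max_rows < 2) max_rows = 2;
  }

  const std::vector<double> &row(int i) {
    if (!have[i]) {
      if (order.size() >= max_rows) {
        int evict = order.front();
        order.erase(order.begin());
        std::vector<double>().swap(rows[evict]);
        have[evict] = 0;
      }
      rows[i].resize(n);
      for (int j = 0; j < n; ++j) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          double diff = X(i, k) - X(j, k);
          s += diff * diff;
        }
        rows[i][j] = std::exp(-gamma * s);
      }
      have[i] = 1;
      order.push_back(i);
    }
    return rows[i];
  }
};

// [[Rcpp::export(name = ".smoTrain")]]
List smoTrain(NumericMatrix X, NumericVector y, double cost, double gamma,
              double eps, int maxIter, double cacheMb) {
  int n = X.nrow();
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  KernelCache cache(X, gamma, (size_t)(cacheMb * 1024.0 * 1024.0));

  int iter = 0;
  bool converged = false;
  while (iter < maxIter) {
    // select i: max over I_up of -y_t G_t ; j: max over I_low of y_t G_t
    int i = -1, j = -1;
    double gmax1 = -HUGE_VAL, gmax2 = -HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      if ((y[t] > 0 && alpha[t] < cost) || (y[t] < 0 && alpha[t] > 0)) {
        double v = -y[t] * G[t];
        if (v > gmax1) { gmax1 = v; i = t; }
      }
      if ((y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < cost)) {
        double v = y[t] * G[t];
        if (v > gmax2) { gmax2 = v; j = t; }
      }
    }
    if (i < 0 || j < 0 || gmax1 + gmax2 < eps) { converged = true; break; }

    const std::vector<double> &Ki = cache.row(i);
    const std::vector<double> &Kj = cache.row(j);
    double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      double quad = Ki[i] + Kj[j] + 2.0 * Ki[j];
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
        if (alpha[i] > cost) { alpha[i] = cost; alpha[j] = cost - diff; }
      } else {
        if (alpha[j] > cost) { alpha[j] = cost; alpha[i] = cost + diff; }
      }
    } else {
      double quad = Ki[i] + Kj[j] - 2.0 * Ki[j];
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > cost) {
        if (alpha[i] > cost) { alpha[i] = cost; alpha[j] = sum - cost; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > cost) {
        if (alpha[j] > cost) { alpha[j] = cost; alpha[i] = sum - cost; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * Ki[t] * dai + y[j] * Kj[t] * daj);
    ++iter;
  }

  // intercept rho: decision is f(x) = sum alpha_t y_t K(x_t, x) - rho
  double ub = HUGE_VAL, lb = -HUGE_VAL, sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = y[t] * G[t];
    if (alpha[t] >= cost) {
      if (y[t] < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 0) {
      if (y[t] > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      ++n_free; sum_free += yG;
    }
  }
  double rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["rho"] = rho, _["iterations"] = iter,
                      _["converged"] = converged);
}

// Decision values sum_s coef_s * exp(-gamma |x - sv_s|^2) - rho for each
// query row; coef = alpha * y of the support vectors.
// [[Rcpp::export(name = ".svmDecision")]]
NumericVector svmDecision(NumericMatrix Xq, NumericMatrix SV,
                          NumericVector coef, double rho, double gamma) {
  int nq = Xq.nrow(), ns = SV.nrow(), d = Xq.ncol();
  if (SV.ncol() != d) stop("feature dimension mismatch");
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double acc = 0.0;
    for (int s = 0; s < ns; ++s) {
      double dist2 = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = Xq(q, k) - SV(s, k);
        dist2 += diff * diff;
      }
      acc += coef[s] * std::exp(-gamma * dist2);
    }
    out[q] = acc - rho;
  }
  return out;
}
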