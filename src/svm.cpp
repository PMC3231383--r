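// C-support-vector classification with an RBF kernel, solved by sequential
// minimal optimisation (maximal-violating-pair working-set selection).
// Written against the standard dual formulation:
//   min_a  1/2 a' Q a - e' a,  0 <= a_i <= C,  y' a = 0,  Q_ij = y_i y_j K_ij
// Multiclass handled by one-vs-one voting. Only dense, small-n problems are
// targeted (n of order a few hundred); the full kernel matrix is precomputed.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double TAU = 1e-12;

// squared Euclidean distance between rows i of A and j of B
static inline double row_sqdist(const NumericMatrix &A, int i,
                                const NumericMatrix &B, int j) {
  double s = 0.0;
  const int d = A.ncol();
  for (int k = 0; k < d; ++k) {
    const double diff = A(i, k) - B(j, k);
    s += diff * diff;
  }
  return s;
}

struct SmoResult {
  std::vector<double> alpha;
  double rho;
  int iter;
};

// K: n x n kernel values for the training subset (row-major, vector form)
// y: labels in {-1, +1}
static SmoResult smo_solve(const std::vector<double> &K,
                           const std::vector<int> &y,
                           int n, double C, double eps, int max_iter) {
  std::vector<double> alpha(n, 0.0);
  // gradient of the dual objective; with alpha = 0, G_i = -1
  std::vector<double> G(n, -1.0);

  int iter = 0;
  while (iter < max_iter) {
    // working-set selection: i maximises -y_i G_i over I_up,
    // j minimises -y_j G_j over I_low
    int i = -1, j = -1;
    double m_up = -std::numeric_limits<double>::infinity();
    double m_low = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const bool in_up = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0.0);
      const bool in_low = (y[t] == 1) ? (alpha[t] > 0.0) : (alpha[t] < C);
      const double v = -y[t] * G[t];
      if (in_up && v > m_up) { m_up = v; i = t; }
      if (in_low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < eps) break;

    // optimal unconstrained step along the feasible pair direction
    double a = K[(size_t)i * n + i] + K[(size_t)j * n + j]
             - 2.0 * K[(size_t)i * n + j];
    if (a < TAU) a = TAU;
    double t_step = (m_up - m_low) / a;

    // box constraints on the step
    const double bound_i = (y[i] == 1) ? (C - alpha[i]) : alpha[i];
    const double bound_j = (y[j] == 1) ? alpha[j] : (C - alpha[j]);
    if (t_step > bound_i) t_step = bound_i;
    if (t_step > bound_j) t_step = bound_j;

    // feasible direction: d alpha_i = +y_i * t, d alpha_j = -y_j * t
    alpha[i] += y[i] * t_step;
    alpha[j] -= y[j] * t_step;

    // gradient update: dG_k = y_k * t * (K_ki - K_kj)
    for (int k = 0; k < n; ++k) {
      G[k] += y[k] * t_step * (K[(size_t)k * n + i] - K[(size_t)k * n + j]);
    }
    ++iter;
  }

  // rho as in the usual C-SVC rule: average y_i G_i over free vectors,
  // else midpoint of the active bounds
  double ub = std::numeric_limits<double>::infinity();
  double lb = -std::numeric_limits<double>::infinity();
  double sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];
    if (alpha[t] >= C - 1e-12) {
      if (y[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 1e-12) {
      if (y[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else {
      sum_free += yG;
      ++n_free;
    }
  }
  SmoResult res;
  res.alpha = alpha;
  res.rho = (n_free > 0) ? sum_free / n_free : (ub + lb) / 2.0;
  res.iter = iter;
  return res;
}

// decision value for a test column of kernel evaluations k(x_t, x_i)
static inline double decision_value(const SmoResult &m,
                                    const std::vector<int> &y,
                                    const std::vector<double> &ktest) {
  double f = 0.0;
  const int n = (int)y.size();
  for (int t = 0; t < n; ++t) f += m.alpha[t] * y[t] * ktest[t];
  return f - m.rho;
}

// One-vs-one vote over all class pairs present in the training labels.
// classes are encoded 1..k; ties go to the smallest class index.
static std::vector<int> ovo_predict(const NumericMatrix &Xtr,
                                    const std::vector<int> &ytr,
                                    const NumericMatrix &Xte,
                                    int k, double C, double gamma,
                                    double eps, int max_iter) {
  const int ntr = Xtr.nrow(), nte = Xte.nrow();

  // full training kernel
  std::vector<double> Kfull((size_t)ntr * ntr);
  for (int i = 0; i < ntr; ++i) {
    Kfull[(size_t)i * ntr + i] = 1.0;
    for (int j = i + 1; j < ntr; ++j) {
      const double v = std::exp(-gamma * row_sqdist(Xtr, i, Xtr, j));
      Kfull[(size_t)i * ntr + j] = v;
      Kfull[(size_t)j * ntr + i] = v;
    }
  }
  // test-vs-train kernel
  std::vector<double> Kte((size_t)nte * ntr);
  for (int i = 0; i < nte; ++i)
    for (int j = 0; j < ntr; ++j)
      Kte[(size_t)i * ntr + j] = std::exp(-gamma * row_sqdist(Xte, i, Xtr, j));

  std::vector<int> votes((size_t)nte * k, 0);
  std::vector<int> present(k, 0);
  for (int i = 0; i < ntr; ++i) present[ytr[i] - 1] = 1;

  for (int a = 0; a < k; ++a) {
    if (!present[a]) continue;
    for (int b = a + 1; b < k; ++b) {
      if (!present[b]) continue;
      std::vector<int> idx;
      std::vector<int> ysub;
      for (int i = 0; i < ntr; ++i) {
        if (ytr[i] - 1 == a) { idx.push_back(i); ysub.push_back(1); }
        else if (ytr[i] - 1 == b) { idx.push_back(i); ysub.push_back(-1); }
      }
      const int m = (int)idx.size();
      std::vector<double> Ksub((size_t)m * m);
      for (int p = 0; p < m; ++p)
        for (int q = 0; q < m; ++q)
          Ksub[(size_t)p * m + q] = Kfull[(size_t)idx[p] * ntr + idx[q]];
      SmoResult mod = smo_solve(Ksub, ysub, m, C, eps, max_iter);

      std::vector<double> kcol(m);
      for (int t = 0; t < nte; ++t) {
        for (int p = 0; p < m; ++p) kcol[p] = Kte[(size_t)t * ntr + idx[p]];
        const double f = decision_value(mod, ysub, kcol);
        if (f > 0) ++votes[(size_t)t * k + a]; else ++votes[(size_t)t * k + b];
      }
    }
  }

  std::vector<int> pred(nte);
  for (int t = 0; t < nte; ++t) {
    int best = 0, bestv = -1;
    for (int c = 0; c < k; ++c) {
      const int v = votes[(size_t)t * k + c];
      if (v > bestv) { bestv = v; best = c; }
    }
    pred[t] = best + 1;
  }
  return pred;
}

//' @noRd
// [[Rcpp::export(name = ".svm_fit_predict_cpp")]]
IntegerVector svm_fit_predict_cpp(NumericMatrix Xtrain, IntegerVector ytrain,
                                  NumericMatrix Xtest, int n_classes,
                                  double C, double gamma,
                                  double eps = 1e-3, int max_iter = 200000) {
  std::vector<int> y(ytrain.begin(), ytrain.end());
  std::vector<int> pred = ovo_predict(Xtrain, y, Xtest, n_classes, C, gamma,
                                      eps, max_iter);
  return IntegerVector(pred.begin(), pred.end());
}

//' @noRd
// [[Rcpp::export(name = ".svm_loocv_cpp")]]
IntegerVector svm_loocv_cpp(NumericMatrix X, IntegerVector yin, int n_classes,
                            double C, double gamma,
                            double eps = 1e-3, int max_iter = 200000) {
  const int n = X.nrow(), k = n_classes;
  std::vector<int> y(yin.begin(), yin.end());

  // kernel matrix computed once and reused by every fold
  std::vector<double> Kfull((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    Kfull[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      const double v = std::exp(-gamma * row_sqdist(X, i, X, j));
      Kfull[(size_t)i * n + j] = v;
      Kfull[(size_t)j * n + i] = v;
    }
  }

  IntegerVector pred(n);
  std::vector<int> votes(k);
  for (int held = 0; held < n; ++held) {
    std::fill(votes.begin(), votes.end(), 0);
    std::vector<int> present(k, 0);
    for (int i = 0; i < n; ++i) if (i != held) present[y[i] - 1] = 1;

    for (int a = 0; a < k; ++a) {
      if (!present[a]) continue;
      for (int b = a + 1; b < k; ++b) {
        if (!present[b]) continue;
        std::vector<int> idx;
        std::vector<int> ysub;
        for (int i = 0; i < n; ++i) {
          if (i == held) continue;
          if (y[i] - 1 == a) { idx.push_back(i); ysub.push_back(1); }
          else if (y[i] - 1 == b) { idx.push_back(i); ysub.push_back(-1); }
        }
        const int m = (int)idx.size();
        std::vector<double> Ksub((size_t)m * m);
        for (int p = 0; p < m; ++p)
          for (int q = 0; q < m; ++q)
            Ksub[(size_t)p * m + q] = Kfull[(size_t)idx[p] * n + idx[q]];
        SmoResult mod = smo_solve(Ksub, ysub, m, C, eps, max_iter);

        std::vector<double> kcol(m);
        for (int p = 0; p < m; ++p) kcol[p] = Kfull[(size_t)held * n + idx[p]];
        const double f = decision_value(mod, ysub, kcol);
        if (f > 0) ++votes[a]; else ++votes[b];
      }
    }
    int best = 0, bestv = -1;
    for (int c = 0; c < k; ++c)
      if (votes[c] > bestv) { bestv = votes[c]; best = c; }
    pred[held] = best + 1;
  }
  return pred;
}

//' @noRd
// [[Rcpp::export(name = ".svm_dual_cpp")]]
List svm_dual_cpp(NumericMatrix X, IntegerVector yin, double C, double gamma,
                  double eps = 1e-3, int max_iter = 200000) {
  // binary solver exposed for cross-checking against an independent QP solver
  const int n = X.nrow();
  std::vector<int> y(yin.begin(), yin.end());
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      K[(size_t)i * n + j] = std::exp(-gamma * row_sqdist(X, i, X, j));
  SmoResult m = smo_solve(K, y, n, C, eps, max_iter);

  // dual objective value 1/2 a'Qa - e'a
  double obj = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j)
      s += m.alpha[j] * y[i] * y[j] * K[(size_t)i * n + j];
    obj += 0.5 * m.alpha[i] * s - m.alpha[i];
  }
  return List::create(_["alpha"] = NumericVector(m.alpha.begin(), m.alpha.end()),
                      _["rho"] = m.rho,
                      _["objective"] = obj,
                      _["iterations"] = m.iter);
}
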