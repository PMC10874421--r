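// Compact SMO solver for C-SVC with precomputed RBF kernels.
//
// Used only to score the (C, gamma) grid during inner cross-validation,
// where the number of solver calls (grid size x inner folds x outer folds x
// one-vs-rest binaries) makes per-call R overhead prohibitive. The final
// model in every outer fold is fit by e1071::svm; agreement between the two
// solvers is asserted in the test suite.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SvmModel {
  std::vector<double> alpha;  // alpha_i (0..C)
  double b;
};

// Keerthi-style SMO with maximal-violating-pair selection.
// K: n x n kernel (flat, row-major not needed: symmetric), y in {-1,+1}.
// alpha/F can carry a feasible warm start (e.g. the solution for a smaller
// C, which stays feasible when C grows); pass empty vectors to cold-start.
SvmModel smo_solve(const std::vector<double>& K, const std::vector<int>& y,
                   int n, double C, std::vector<double>& alpha,
                   std::vector<double>& F, double tol = 1e-3,
                   int max_iter = 3000) {
  if ((int)alpha.size() != n) {
    alpha.assign(n, 0.0);
    F.resize(n);
    for (int i = 0; i < n; ++i) F[i] = -y[i];
  }

  std::vector<char> blocked(n);
  for (int iter = 0; iter < max_iter; ++iter) {
    // b_up = min F over I_up, b_low = max F over I_low
    double b_up = R_PosInf, b_low = R_NegInf;
    int i_up = -1;
    for (int t = 0; t < n; ++t) {
      bool in_up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool in_low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      if (in_up && F[t] < b_up) { b_up = F[t]; i_up = t; }
      if (in_low && F[t] > b_low) b_low = F[t];
    }
    if (i_up < 0 || !(b_low > R_NegInf) || b_low - b_up < 2.0 * tol) break;

    double kuu = K[(size_t)i_up * n + i_up];
    std::fill(blocked.begin(), blocked.end(), 0);
    bool progressed = false;
    while (!progressed) {
      // second-order working-set selection: partner maximizing the
      // guaranteed objective decrease (F_t - b_up)^2 / eta_t
      int i_low = -1;
      double best_gain = 0.0;
      for (int t = 0; t < n; ++t) {
        if (blocked[t]) continue;
        bool in_low = (y[t] == 1 && alpha[t] > 0) ||
                      (y[t] == -1 && alpha[t] < C);
        if (!in_low || !(F[t] > b_up + 1e-12)) continue;
        double diff = F[t] - b_up;
        double eta_t = kuu + K[(size_t)t * n + t] -
                       2.0 * K[(size_t)i_up * n + t];
        if (eta_t < 1e-12) eta_t = 1e-12;
        double gain = diff * diff / eta_t;
        if (gain > best_gain) { best_gain = gain; i_low = t; }
      }
      if (i_low < 0) break;

      int i1 = i_low, i2 = i_up;
      double a1 = alpha[i1], a2 = alpha[i2];
      int y1 = y[i1], y2 = y[i2];
      double s = y1 * y2;
      double L, H;
      if (s < 0) { L = std::max(0.0, a2 - a1); H = std::min(C, C + a2 - a1); }
      else       { L = std::max(0.0, a2 + a1 - C); H = std::min(C, a2 + a1); }
      if (H - L < 1e-12) { blocked[i1] = 1; continue; }
      double k11 = K[(size_t)i1 * n + i1], k22 = K[(size_t)i2 * n + i2],
             k12 = K[(size_t)i1 * n + i2];
      double eta = k11 + k22 - 2.0 * k12;
      double E1 = F[i1], E2 = F[i2];
      double a2new;
      if (eta > 1e-12) {
        a2new = a2 + y2 * (E1 - E2) / eta;
        if (a2new < L) a2new = L; else if (a2new > H) a2new = H;
      } else {
        // flat direction: move to the bound that lowers the objective
        double f1 = y1 * E1, f2 = y2 * E2;
        double L1 = a1 + s * (a2 - L), H1 = a1 + s * (a2 - H);
        double psiL = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 +
                      0.5 * L * L * k22 + s * L * L1 * k12;
        double psiH = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 +
                      0.5 * H * H * k22 + s * H * H1 * k12;
        a2new = (psiL < psiH - 1e-12) ? L : H;
      }
      if (std::fabs(a2new - a2) < 1e-12) { blocked[i1] = 1; continue; }
      double a1new = a1 + s * (a2 - a2new);
      alpha[i1] = a1new;
      alpha[i2] = a2new;
      double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2);
      for (int t = 0; t < n; ++t)
        F[t] += d1 * K[(size_t)i1 * n + t] + d2 * K[(size_t)i2 * n + t];
      progressed = true;
    }
    if (!progressed) break;   // the maximal violator cannot move further
  }

  // b from the KKT gap
  double b_up = R_PosInf, b_low = R_NegInf;
  double sv_sum = 0.0; int sv_n = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 && alpha[t] < C - 1e-8) { sv_sum += F[t]; ++sv_n; }
    bool in_up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
    bool in_low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
    if (in_up && F[t] < b_up) b_up = F[t];
    if (in_low && F[t] > b_low) b_low = F[t];
  }
  SvmModel m;
  m.alpha = alpha;
  m.b = sv_n > 0 ? -sv_sum / sv_n : -(b_up + b_low) / 2.0;
  return m;
}

SvmModel smo_solve_cold(const std::vector<double>& K,
                        const std::vector<int>& y, int n, double C,
                        int max_iter = 50000) {
  std::vector<double> alpha, F;
  return smo_solve(K, y, n, C, alpha, F, 1e-3, max_iter);
}

// decision values for test rows given cross-kernel Kt (n_test x n_train)
void decision_values(const std::vector<double>& Kt, int n_test, int n_train,
                     const std::vector<int>& y, const SvmModel& m,
                     std::vector<double>& out) {
  out.assign(n_test, m.b);
  for (int j = 0; j < n_train; ++j) {
    double c = m.alpha[j] * y[j];
    if (c == 0.0) continue;
    for (int i = 0; i < n_test; ++i) out[i] += c * Kt[(size_t)i * n_train + j];
  }
}

}  // namespace

// Train one binary RBF SVM on a precomputed squared-distance matrix and
// return alpha, b, and decision values for the given test rows.
// [[Rcpp::export(name = ".smo_fit_predict")]]
List smo_fit_predict(NumericMatrix D2_train, NumericMatrix D2_test_train,
                     IntegerVector y, double cost, double gamma) {
  int n = D2_train.nrow(), nt = D2_test_train.nrow();
  std::vector<double> K((size_t)n * n), Kt((size_t)nt * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      K[(size_t)i * n + j] = std::exp(-gamma * D2_train(i, j));
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < n; ++j)
      Kt[(size_t)i * n + j] = std::exp(-gamma * D2_test_train(i, j));
  std::vector<int> yy(y.begin(), y.end());
  SvmModel m = smo_solve_cold(K, yy, n, cost);
  std::vector<double> dec;
  decision_values(Kt, nt, n, yy, m, dec);
  return List::create(_["alpha"] = NumericVector(m.alpha.begin(), m.alpha.end()),
                      _["b"] = m.b,
                      _["decision"] = NumericVector(dec.begin(), dec.end()));
}

// Inner-CV accuracy for every (C, gamma) cell.
//
// D2: n x n squared Euclidean distances of the training partition.
// labels: class codes 1..n_classes. fold_id: inner fold assignment 1..n_folds.
// c_grid must be ascending (the solver warm-starts along the C path).
// Returns an (n_C x n_gamma) matrix of pooled inner-CV accuracies; binary
// problems use a single classifier, multiclass uses one-vs-rest with argmax
// over decision values.
// [[Rcpp::export(name = ".svm_grid_cv")]]
NumericMatrix svm_grid_cv(NumericMatrix D2, IntegerVector labels,
                          int n_classes, NumericVector c_grid,
                          NumericVector gamma_grid, IntegerVector fold_id,
                          int n_folds) {
  int n = D2.nrow();
  int nc = c_grid.size(), ng = gamma_grid.size();
  NumericMatrix acc(nc, ng);
  std::vector<double> K((size_t)n * n);

  int n_bin = (n_classes == 2) ? 1 : n_classes;

  for (int g = 0; g < ng; ++g) {
    double gam = gamma_grid[g];
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        K[(size_t)i * n + j] = std::exp(-gam * D2(i, j));

    std::vector<int> n_correct(nc, 0);

    for (int f = 1; f <= n_folds; ++f) {
      std::vector<int> tr, te;
      tr.reserve(n); te.reserve(n);
      for (int i = 0; i < n; ++i)
        (fold_id[i] == f ? te : tr).push_back(i);
      int ntr = (int)tr.size(), nte = (int)te.size();
      if (ntr == 0 || nte == 0) continue;
      std::vector<double> Ktr((size_t)ntr * ntr), Kte((size_t)nte * ntr);
      for (int i = 0; i < ntr; ++i)
        for (int j = 0; j < ntr; ++j)
          Ktr[(size_t)i * ntr + j] = K[(size_t)tr[i] * n + tr[j]];
      for (int i = 0; i < nte; ++i)
        for (int j = 0; j < ntr; ++j)
          Kte[(size_t)i * ntr + j] = K[(size_t)te[i] * n + tr[j]];

      // warm-start state per binary task, reused along the ascending C path
      std::vector<std::vector<double>> wa(n_bin), wf(n_bin);
      std::vector<std::vector<int>> ys(n_bin);
      for (int b = 0; b < n_bin; ++b) {
        int pos = (n_classes == 2) ? 1 : (b + 1);
        ys[b].resize(ntr);
        for (int i = 0; i < ntr; ++i)
          ys[b][i] = (labels[tr[i]] == pos) ? 1 : -1;
      }
      for (int ci = 0; ci < nc; ++ci) {
        double C = c_grid[ci];
        std::vector<std::vector<double>> dec(n_bin);
        for (int b = 0; b < n_bin; ++b) {
          SvmModel m = smo_solve(Ktr, ys[b], ntr, C, wa[b], wf[b]);
          decision_values(Kte, nte, ntr, ys[b], m, dec[b]);
        }
        for (int i = 0; i < nte; ++i) {
          int pred;
          if (n_classes == 2) {
            pred = dec[0][i] >= 0 ? 1 : 2;
          } else {
            pred = 1;
            double best = dec[0][i];
            for (int b = 1; b < n_bin; ++b)
              if (dec[b][i] > best) { best = dec[b][i]; pred = b + 1; }
          }
          if (pred == labels[te[i]]) ++n_correct[ci];
        }
      }
    }
    for (int ci = 0; ci < nc; ++ci) acc(ci, g) = (double)n_correct[ci] / n;
  }
  return acc;
}
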