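// Dense two-phase primal simplex for small enzyme-constrained FBA problems.
//
// Deterministic by construction: variable order is the column order of the
// input matrix, the entering rule is Dantzig's (most negative reduced cost)
// with a switch to Bland's rule after a fixed iteration budget to guarantee
// termination on degenerate polytopes, and ratio-test ties are broken by the
// smallest basic variable index.  Repeated calls with identical input return
// bit-identical solutions, which the lexicographic optimiser relies on when
// comparing non-parsimonious and parsimonious solutions.

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tableau {
  int M;                 // rows (constraints)
  int N;                 // columns (structural + slack + artificial)
  std::vector<double> a; // M x N, row-major
  std::vector<double> b; // rhs, length M
  std::vector<double> cost1, cost2; // phase-1 / phase-2 reduced-cost rows
  double z1, z2;         // negated objective values of the two phases
  std::vector<int> basis;

  double& at(int i, int j) { return a[static_cast<size_t>(i) * N + j]; }

  void pivot(int pr, int pc) {
    const double piv = at(pr, pc);
    const double inv = 1.0 / piv;
    for (int j = 0; j < N; ++j) at(pr, j) *= inv;
    b[pr] *= inv;
    at(pr, pc) = 1.0; // kill round-off on the pivot element
    for (int i = 0; i < M; ++i) {
      if (i == pr) continue;
      const double f = at(i, pc);
      if (f == 0.0) continue;
      for (int j = 0; j < N; ++j) at(i, j) -= f * at(pr, j);
      at(i, pc) = 0.0;
      b[i] -= f * b[pr];
      if (b[i] < 0.0 && b[i] > -1e-11) b[i] = 0.0;
    }
    double f1 = cost1[pc];
    if (f1 != 0.0) {
      for (int j = 0; j < N; ++j) cost1[j] -= f1 * at(pr, j);
      cost1[pc] = 0.0;
      z1 -= f1 * b[pr];
    }
    double f2 = cost2[pc];
    if (f2 != 0.0) {
      for (int j = 0; j < N; ++j) cost2[j] -= f2 * at(pr, j);
      cost2[pc] = 0.0;
      z2 -= f2 * b[pr];
    }
    basis[pr] = pc;
  }
};

// Returns 0 optimal, 2 unbounded, 3 iteration limit.
int run_phase(Tableau& T, const std::vector<double>& cost_live,
              bool phase_one, int max_col, double tol, int max_iter,
              int bland_after) {
  (void)cost_live;
  for (int iter = 0; iter < max_iter; ++iter) {
    const std::vector<double>& c = phase_one ? T.cost1 : T.cost2;
    const bool bland = iter >= bland_after;
    int pc = -1;
    double best = -tol;
    for (int j = 0; j < max_col; ++j) {
      if (c[j] < best) {
        pc = j;
        if (bland) break; // first (smallest-index) improving column
        best = c[j];
      }
    }
    if (pc < 0) return 0; // optimal
    int pr = -1;
    double best_ratio = std::numeric_limits<double>::infinity();
    for (int i = 0; i < T.M; ++i) {
      const double aij = T.at(i, pc);
      if (aij > tol) {
        const double ratio = T.b[i] / aij;
        if (ratio < best_ratio - 1e-12 ||
            (ratio < best_ratio + 1e-12 && pr >= 0 &&
             T.basis[i] < T.basis[pr])) {
          best_ratio = ratio;
          pr = i;
        }
      }
    }
    if (pr < 0) return 2; // unbounded
    T.pivot(pr, pc);
  }
  return 3;
}

} // namespace

// [[Rcpp::export(name = ".simplex_lp")]]
List simplex_lp(NumericMatrix A, NumericVector rhs, IntegerVector sense,
                NumericVector lb, NumericVector ub, NumericVector obj,
                bool maximize, double tol = 1e-9, int max_iter = 20000) {
  const int m0 = A.nrow();
  const int n0 = A.ncol();
  if (rhs.size() != m0 || sense.size() != m0)
    stop("rhs/sense length must match nrow(A)");
  if (lb.size() != n0 || ub.size() != n0 || obj.size() != n0)
    stop("lb/ub/obj length must match ncol(A)");

  std::vector<double> x(n0, 0.0);
  auto finish = [&](int status) {
    double z = 0.0;
    for (int j = 0; j < n0; ++j) z += obj[j] * x[j];
    return List::create(_["status"] = status, _["x"] = NumericVector(x.begin(), x.end()),
                        _["objective"] = z);
  };

  for (int j = 0; j < n0; ++j) {
    if (!std::isfinite(lb[j]))
      stop("all variable lower bounds must be finite (irreversible form)");
    if (ub[j] - lb[j] < -tol) return finish(1); // empty box
  }

  // Shifted variables y = x - lb, y >= 0; finite upper bounds become rows.
  std::vector<int> ub_rows;
  for (int j = 0; j < n0; ++j)
    if (std::isfinite(ub[j])) ub_rows.push_back(j);
  const int M = m0 + static_cast<int>(ub_rows.size());

  // Row data in shifted coordinates with b >= 0.
  std::vector<std::vector<double>> rows(M, std::vector<double>(n0, 0.0));
  std::vector<double> brow(M);
  std::vector<int> srow(M); // sense after sign fix: -1 le, 0 eq, 1 ge
  for (int i = 0; i < m0; ++i) {
    double bi = rhs[i];
    for (int j = 0; j < n0; ++j) {
      rows[i][j] = A(i, j);
      bi -= A(i, j) * lb[j];
    }
    brow[i] = bi;
    srow[i] = sense[i];
  }
  for (size_t k = 0; k < ub_rows.size(); ++k) {
    const int i = m0 + static_cast<int>(k);
    const int j = ub_rows[k];
    rows[i][j] = 1.0;
    brow[i] = ub[j] - lb[j];
    srow[i] = -1;
  }
  for (int i = 0; i < M; ++i) {
    if (brow[i] < 0.0) {
      for (int j = 0; j < n0; ++j) rows[i][j] = -rows[i][j];
      brow[i] = -brow[i];
      srow[i] = -srow[i];
    }
  }

  int n_slack = 0, n_art = 0;
  std::vector<int> slack_col(M, -1), art_col(M, -1);
  for (int i = 0; i < M; ++i)
    if (srow[i] != 0) slack_col[i] = n_slack++;
  for (int i = 0; i < M; ++i)
    if (srow[i] != -1) art_col[i] = n_art++; // ge and eq rows need artificials

  Tableau T;
  T.M = M;
  T.N = n0 + n_slack + n_art;
  T.a.assign(static_cast<size_t>(M) * T.N, 0.0);
  T.b = brow;
  T.basis.assign(M, -1);
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j < n0; ++j) T.at(i, j) = rows[i][j];
    if (slack_col[i] >= 0)
      T.at(i, n0 + slack_col[i]) = (srow[i] == -1) ? 1.0 : -1.0;
    if (art_col[i] >= 0) T.at(i, n0 + n_slack + art_col[i]) = 1.0;
    T.basis[i] = (srow[i] == -1) ? (n0 + slack_col[i]) : (n0 + n_slack + art_col[i]);
  }

  // Phase-2 cost row (minimisation form).
  T.cost2.assign(T.N, 0.0);
  const double sgn = maximize ? -1.0 : 1.0;
  for (int j = 0; j < n0; ++j) T.cost2[j] = sgn * obj[j];
  T.z2 = 0.0;

  // Phase-1 cost row: sum of artificials, reduced against the initial basis.
  T.cost1.assign(T.N, 0.0);
  T.z1 = 0.0;
  for (int i = 0; i < M; ++i) {
    if (art_col[i] >= 0) {
      for (int j = 0; j < T.N; ++j) T.cost1[j] -= T.at(i, j);
      T.cost1[n0 + n_slack + art_col[i]] = 0.0;
      T.z1 -= T.b[i];
    }
  }

  const int bland_after = 500 + 20 * (M + T.N);
  if (n_art > 0) {
    int st = run_phase(T, T.cost1, true, T.N, tol, max_iter, bland_after);
    if (st == 3) stop("simplex iteration limit reached in phase 1");
    if (-T.z1 > 1e-7) return finish(1); // infeasible
    // Drive remaining artificials out of the basis where possible.
    for (int i = 0; i < M; ++i) {
      if (T.basis[i] >= n0 + n_slack) {
        int pc = -1;
        for (int j = 0; j < n0 + n_slack; ++j) {
          if (std::fabs(T.at(i, j)) > tol) { pc = j; break; }
        }
        if (pc >= 0) T.pivot(i, pc);
        // else: redundant all-zero row, inert from here on
      }
    }
  }

  int st = run_phase(T, T.cost2, false, n0 + n_slack, tol, max_iter, bland_after);
  if (st == 3) stop("simplex iteration limit reached in phase 2");
  if (st == 2) {
    for (int i = 0; i < T.M; ++i)
      if (T.basis[i] < n0) x[T.basis[i]] = lb[T.basis[i]] + T.b[i];
    return finish(2); // unbounded (x holds the last vertex visited)
  }

  for (int j = 0; j < n0; ++j) x[j] = lb[j];
  for (int i = 0; i < M; ++i)
    if (T.basis[i] < n0) x[T.basis[i]] = lb[T.basis[i]] + T.b[i];
  return finish(0);
}
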