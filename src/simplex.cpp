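// Dense two-phase primal simplex for small/medium LPs.
//
// Solves: maximize c'x  subject to  A x <= b,  x >= 0
// (b may have any sign; upper bounds on variables are passed as explicit
// rows by the R wrapper).  Dantzig pricing with a Bland fallback after a
// fixed number of iterations guards against cycling.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <unordered_map>

using namespace Rcpp;

static const double EPS = 1e-9;

// [[Rcpp::export(name = ".cpp_simplex")]]
List cpp_simplex(NumericMatrix A, NumericVector b, NumericVector c,
                 int max_iter = 50000) {
  const int m = A.nrow(), n = A.ncol();

  // Count artificials (rows with negative rhs).
  std::vector<int> art_row;
  for (int i = 0; i < m; ++i) if (b[i] < 0.0) art_row.push_back(i);
  const int n_art = (int) art_row.size();
  const int ncols = n + m + n_art;           // structural + slack + artificial

  // Tableau rows: m constraints; columns: ncols + rhs.
  std::vector< std::vector<double> > T(m, std::vector<double>(ncols + 1, 0.0));
  std::vector<int> basis(m);

  int ak = 0;
  std::vector<int> art_col(m, -1);
  for (int i = 0; i < m; ++i) {
    double sgn = (b[i] < 0.0) ? -1.0 : 1.0;
    for (int j = 0; j < n; ++j) T[i][j] = sgn * A(i, j);
    T[i][n + i] = sgn;                        // slack (negated if row flipped)
    T[i][ncols] = sgn * b[i];
    if (b[i] < 0.0) {
      art_col[i] = n + m + ak;
      T[i][art_col[i]] = 1.0;
      basis[i] = art_col[i];
      ++ak;
    } else {
      basis[i] = n + i;
    }
  }

  // Objective row z: reduced costs; phase 1 minimises the artificial sum,
  // expressed as maximise -sum(artificials).
  std::vector<double> z(ncols + 1, 0.0);
  for (int i = 0; i < m; ++i) {
    if (art_col[i] >= 0) {
      for (int j = 0; j <= ncols; ++j) z[j] += T[i][j];
    }
  }
  // z holds row-sums over artificial rows; reduced cost for phase 1 of column
  // j is -z[j] (we maximise -sum art); we pivot on positive z entries.

  int iter = 0, phase = (n_art > 0) ? 1 : 2;
  bool bland = false;

  // Set up phase-2 objective immediately if no artificials.
  if (phase == 2) {
    for (int j = 0; j < n; ++j) z[j] = -c[j];
    z[ncols] = 0.0;
  }

  while (true) {
    if (++iter > max_iter) return List::create(_["status"] = 3);
    if (iter > max_iter / 2) bland = true;

    // Entering column: in phase 1 pick z[j] > EPS (reduces infeasibility);
    // in phase 2 pick z[j] < -EPS (improves objective).
    int enter = -1;
    double best = 0.0;
    for (int j = 0; j < n + m; ++j) {               // artificials never enter
      double v = (phase == 1) ? z[j] : -z[j];
      if (v > EPS) {
        if (bland) { enter = j; break; }
        if (v > best) { best = v; enter = j; }
      }
    }

    if (enter < 0) {
      if (phase == 1) {
        if (z[ncols] > 1e-7) return List::create(_["status"] = 1); // infeasible
        // Drive any residual artificials out of the basis (degenerate rows).
        for (int i = 0; i < m; ++i) {
          if (basis[i] >= n + m) {
            int piv = -1;
            for (int j = 0; j < n + m; ++j)
              if (std::fabs(T[i][j]) > EPS) { piv = j; break; }
            if (piv >= 0) {
              double p = T[i][piv];
              for (int j = 0; j <= ncols; ++j) T[i][j] /= p;
              for (int r = 0; r < m; ++r) {
                if (r == i) continue;
                double f = T[r][piv];
                if (std::fabs(f) > 0) for (int j = 0; j <= ncols; ++j) T[r][j] -= f * T[i][j];
              }
              basis[i] = piv;
            }
            // else: row is all-zero => redundant constraint, leave it.
          }
        }
        // Build phase-2 reduced costs: z = -c priced out over the basis.
        for (int j = 0; j <= ncols; ++j) z[j] = 0.0;
        for (int j = 0; j < n; ++j) z[j] = -c[j];
        for (int i = 0; i < m; ++i) {
          if (basis[i] < n && std::fabs(c[basis[i]]) > 0) {
            double f = c[basis[i]];
            for (int j = 0; j <= ncols; ++j) z[j] += f * T[i][j];
          }
        }
        phase = 2;
        bland = false;
        iter = 0;
        continue;
      }
      break;  // phase 2 optimal
    }

    // Ratio test.
    int leave = -1;
    double best_ratio = std::numeric_limits<double>::infinity();
    for (int i = 0; i < m; ++i) {
      if (T[i][enter] > EPS) {
        double r = T[i][ncols] / T[i][enter];
        if (r < best_ratio - EPS ||
            (r < best_ratio + EPS && leave >= 0 && basis[i] < basis[leave])) {
          best_ratio = r;
          leave = i;
        }
      }
    }
    if (leave < 0) return List::create(_["status"] = 2);  // unbounded

    // Pivot.
    double p = T[leave][enter];
    for (int j = 0; j <= ncols; ++j) T[leave][j] /= p;
    for (int i = 0; i < m; ++i) {
      if (i == leave) continue;
      double f = T[i][enter];
      if (std::fabs(f) > 0)
        for (int j = 0; j <= ncols; ++j) T[i][j] -= f * T[leave][j];
    }
    double fz = z[enter];
    if (std::fabs(fz) > 0)
      for (int j = 0; j <= ncols; ++j) z[j] -= fz * T[leave][j];
    basis[leave] = enter;
  }

  NumericVector x(n);
  for (int i = 0; i < m; ++i)
    if (basis[i] < n) x[basis[i]] = T[i][ncols];
  double obj = 0.0;
  for (int j = 0; j < n; ++j) obj += c[j] * x[j];
  return List::create(_["status"] = 0, _["x"] = x, _["objective"] = obj);
}

// One lazy-propagation step of the ensemble-averaged Markov kernel over
// binary network states.  States are encoded as integers (double-valued,
// exact for n <= 30).  For every support state and every model, applies
// the synchronous Heaviside update with `clamp_idx` modules (0-based)
// held at 1, and accumulates mass/k onto the image code.
// [[Rcpp::export(name = ".cpp_markov_step")]]
List cpp_markov_step(NumericVector Jflat, int n, int k,
                     NumericVector codes, NumericVector mass,
                     IntegerVector clamp_idx, double phi0) {
  const double *J = Jflat.begin();
  std::unordered_map<double, double> acc;
  std::vector<double> s(n), pow2(n);
  for (int i = 0; i < n; ++i) pow2[i] = std::ldexp(1.0, i);
  std::vector<bool> clamped(n, false);
  for (int ci : clamp_idx) clamped[ci] = true;
  for (int w = 0; w < codes.size(); ++w) {
    long long code = (long long) codes[w];
    for (int i = 0; i < n; ++i) s[i] = (code >> i) & 1LL;
    for (int ci = 0; ci < (int) clamp_idx.size(); ++ci) s[clamp_idx[ci]] = 1.0;
    double m_over_k = mass[w] / k;
    for (int q = 0; q < k; ++q) {
      const double *Jq = J + (size_t) q * n * n;
      double newcode = 0.0;
      for (int i = 0; i < n; ++i) {
        double v;
        if (clamped[i]) v = 1.0;
        else {
          double drive = 0.0;
          for (int j = 0; j < n; ++j) drive += Jq[i + (size_t) j * n] * s[j];
          v = (drive - phi0 >= 0.0) ? 1.0 : 0.0;
        }
        if (v > 0.5) newcode += pow2[i];
      }
      acc[newcode] += m_over_k;
    }
  }
  NumericVector out_codes(acc.size()), out_mass(acc.size());
  int idx = 0;
  for (auto &kv : acc) { out_codes[idx] = kv.first; out_mass[idx] = kv.second; ++idx; }
  return List::create(_["codes"] = out_codes, _["mass"] = out_mass);
}

// Synchronous Heaviside update for a whole ensemble: for each model k,
// new state m_i = H(sum_j J_ij s_j - phi0) with H(x >= 0) = 1.
// J is passed as an n x n x k array flattened column-major; s is the level
// vector (may exceed 1 for clamped modules); update_mask marks modules that
// are updated (clamped modules keep their level).
// [[Rcpp::export(name = ".cpp_step_ensemble")]]
IntegerMatrix cpp_step_ensemble(NumericVector Jflat, int n, int k,
                                NumericVector s, LogicalVector update_mask,
                                double phi0) {
  IntegerMatrix out(n, k);
  const double *J = Jflat.begin();
  for (int q = 0; q < k; ++q) {
    const double *Jq = J + (size_t) q * n * n;
    for (int i = 0; i < n; ++i) {
      if (!update_mask[i]) { out(i, q) = -1; continue; }  // caller re-fills
      double drive = 0.0;
      for (int j = 0; j < n; ++j) drive += Jq[i + (size_t) j * n] * s[j];
      out(i, q) = (drive - phi0 >= 0.0) ? 1 : 0;
    }
  }
  return out;
}
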