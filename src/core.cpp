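#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// Strategy codes (0-based internally, 1-based at the R interface):
//   0 = CN (cooperate, no punishment)
//   1 = DN (defect, no punishment)
//   2 = CP (cooperate, punish defectors)
//   3 = DP (defect, punish defectors)
// Punishment mode: 0 = none, 1 = direct (first-order scope),
//                  2 = indirect (second-order scope).

namespace {

struct Tables {
  std::vector<int> n1; // N x 8 first-order (Moore) neighbours
  std::vector<int> n2; // N x 16 second-order (Chebyshev distance 2) ring
};

// Neighbour offsets are enumerated in (dr, dc) lexicographic order; the R
// helpers use the same order so seeded update sequences agree exactly.
Tables build_tables(int L) {
  const int N = L * L;
  Tables t;
  t.n1.resize(static_cast<size_t>(N) * 8);
  t.n2.resize(static_cast<size_t>(N) * 16);
  for (int c = 0; c < L; ++c) {
    for (int r = 0; r < L; ++r) {
      const int i = r + c * L; // column-major, matching R matrices
      int k1 = 0, k2 = 0;
      for (int dr = -2; dr <= 2; ++dr) {
        for (int dc = -2; dc <= 2; ++dc) {
          const int cheb = std::max(std::abs(dr), std::abs(dc));
          if (cheb == 0) continue;
          const int rr = (r + dr + L) % L;
          const int cc = (c + dc + L) % L;
          const int j = rr + cc * L;
          if (cheb == 1) t.n1[static_cast<size_t>(i) * 8 + k1++] = j;
          else           t.n2[static_cast<size_t>(i) * 16 + k2++] = j;
        }
      }
    }
  }
  return t;
}

// Row-player payoff tables, a[focal * 4 + opponent].
// Stage 1: R = 1, P = 0, T = 1 + r, S = -r (depends only on C/D).
// Stage 2: punisher pays gamma per defector in scope, defector is fined
// beta per punisher holding it in scope.
void fill_payoff_tables(double r, double beta, double gam, int mode,
                        double *a1, double *a2) {
  for (int f = 0; f < 4; ++f) {
    const bool f_coop = (f == 0 || f == 2);
    const bool f_pun  = (f >= 2);
    for (int o = 0; o < 4; ++o) {
      const bool o_coop = (o == 0 || o == 2);
      const bool o_pun  = (o >= 2);
      double v;
      if (f_coop)      v = o_coop ? 1.0 : -r;
      else             v = o_coop ? 1.0 + r : 0.0;
      a1[f * 4 + o] = v;
      double w = 0.0;
      if (mode != 0) {
        if (f_pun && !o_coop) w -= gam;   // cost of punishing a defector
        if (!f_coop && o_pun) w -= beta;  // fine received from a punisher
      }
      a2[f * 4 + o] = w;
    }
  }
}

inline double payoff_at(const std::vector<int> &s, int i, const Tables &t,
                        const double *a1, const double *a2, int mode) {
  const int si = s[i];
  double p = 0.0;
  const int *f = &t.n1[static_cast<size_t>(i) * 8];
  for (int k = 0; k < 8; ++k) p += a1[si * 4 + s[f[k]]];
  if (mode == 1) {
    for (int k = 0; k < 8; ++k) p += a2[si * 4 + s[f[k]]];
  } else if (mode == 2) {
    const int *g = &t.n2[static_cast<size_t>(i) * 16];
    for (int k = 0; k < 16; ++k) p += a2[si * 4 + s[g[k]]];
  }
  return p;
}

IntegerMatrix dump_grid(const std::vector<int> &s, int L) {
  IntegerMatrix out(L, L);
  for (int i = 0; i < L * L; ++i) out[i] = s[i] + 1;
  return out;
}

} // namespace

// [[Rcpp::export]]
List neighbor_tables_cpp(int L) {
  if (L < 5) stop("lattice side L must be at least 5");
  Tables t = build_tables(L);
  const int N = L * L;
  IntegerMatrix m1(N, 8), m2(N, 16);
  for (int i = 0; i < N; ++i) {
    for (int k = 0; k < 8; ++k)  m1(i, k) = t.n1[static_cast<size_t>(i) * 8 + k] + 1;
    for (int k = 0; k < 16; ++k) m2(i, k) = t.n2[static_cast<size_t>(i) * 16 + k] + 1;
  }
  return List::create(_["first"] = m1, _["second"] = m2);
}

// Asynchronous Monte Carlo evolution with Fermi pairwise imitation.
// One Monte Carlo step = N elementary updates; each update draws three
// uniforms (focal site, model neighbour, acceptance) from R's RNG so that
// results are reproducible through set.seed() and agree with the pure-R
// reference updater.
// [[Rcpp::export]]
List sim_run_cpp(IntegerMatrix grid0, double r, double beta, double gam,
                 double kappa, int mode, int steps,
                 IntegerVector snapshot_steps, bool collect_ledger) {
  const int L = grid0.nrow();
  if (grid0.ncol() != L) stop("grid must be square");
  if (L < 5) stop("lattice side L must be at least 5");
  if (steps < 0) stop("steps must be non-negative");
  const int N = L * L;
  const Tables tb = build_tables(L);

  double a1[16], a2[16];
  fill_payoff_tables(r, beta, gam, mode, a1, a2);

  std::vector<int> s(N);
  int cnt[4] = {0, 0, 0, 0};
  for (int i = 0; i < N; ++i) {
    const int v = grid0[i] - 1;
    if (v < 0 || v > 3) stop("strategy codes must lie in 1..4");
    s[i] = v;
    ++cnt[v];
  }

  NumericMatrix frac(steps + 1, 4);
  for (int q = 0; q < 4; ++q) frac(0, q) = static_cast<double>(cnt[q]) / N;

  IntegerMatrix imposed(collect_ledger ? steps : 0, 16);
  IntegerMatrix received(collect_ledger ? steps : 0, 16);

  std::vector<bool> snap_at(steps + 1, false);
  int last_snap = -1;
  for (int k = 0; k < snapshot_steps.size(); ++k) {
    const int t = snapshot_steps[k];
    if (t >= 0 && t <= steps) {
      snap_at[t] = true;
      if (t > last_snap) last_snap = t;
    }
  }
  std::vector<IntegerMatrix> snaps;
  std::vector<int> snap_when;
  if (steps >= 0 && last_snap >= 0 && snap_at[0]) {
    snaps.push_back(dump_grid(s, L));
    snap_when.push_back(0);
  }

  int absorbed = -1;
  const double clamp = 700.0;

  for (int step = 1; step <= steps; ++step) {
    const bool mono =
        (cnt[0] == N || cnt[1] == N || cnt[2] == N || cnt[3] == N);
    if (mono && absorbed < 0) absorbed = step - 1;
    if (!mono) {
      for (int u = 0; u < N; ++u) {
        const double u1 = unif_rand();
        const double u2 = unif_rand();
        const double u3 = unif_rand();
        int i = static_cast<int>(u1 * N);
        if (i >= N) i = N - 1;
        int jk = static_cast<int>(u2 * 8);
        if (jk >= 8) jk = 7;
        const int j = tb.n1[static_cast<size_t>(i) * 8 + jk];
        if (s[i] != s[j]) {
          const double pi = payoff_at(s, i, tb, a1, a2, mode);
          const double pj = payoff_at(s, j, tb, a1, a2, mode);
          double x = (pi - pj) * kappa;
          if (x > clamp) x = clamp;
          else if (x < -clamp) x = -clamp;
          if (u3 < 1.0 / (1.0 + std::exp(x))) {
            --cnt[s[i]];
            s[i] = s[j];
            ++cnt[s[i]];
          }
        }
      }
    }
    for (int q = 0; q < 4; ++q) frac(step, q) = static_cast<double>(cnt[q]) / N;

    if (collect_ledger && mode != 0) {
      const int len = (mode == 1) ? 8 : 16;
      for (int i = 0; i < N; ++i) {
        const int si = s[i];
        const bool pun = (si >= 2);
        const bool def = (si == 1 || si == 3);
        if (!pun && !def) continue;
        const int *scope = (mode == 1) ? &tb.n1[static_cast<size_t>(i) * 8]
                                       : &tb.n2[static_cast<size_t>(i) * 16];
        int nd = 0, np = 0;
        for (int k = 0; k < len; ++k) {
          const int sj = s[scope[k]];
          nd += (sj == 1 || sj == 3);
          np += (sj >= 2);
        }
        if (pun && nd > 0) ++imposed(step - 1, nd - 1);
        if (def && np > 0) ++received(step - 1, np - 1);
      }
    }
    if (snap_at[step]) {
      snaps.push_back(dump_grid(s, L));
      snap_when.push_back(step);
    }

    // A monomorphic population is absorbing: once every later observation
    // is determined, copy it forward instead of burning RNG draws.
    if (mono && !collect_ledger && step >= last_snap) {
      for (int t = step + 1; t <= steps; ++t)
        for (int q = 0; q < 4; ++q) frac(t, q) = frac(step, q);
      break;
    }
    if ((step & 255) == 0) Rcpp::checkUserInterrupt();
  }
  if (absorbed < 0 &&
      (cnt[0] == N || cnt[1] == N || cnt[2] == N || cnt[3] == N))
    absorbed = steps;

  List snl(snaps.size());
  CharacterVector snn(snaps.size());
  for (size_t k = 0; k < snaps.size(); ++k) {
    snl[k] = snaps[k];
    snn[k] = std::to_string(snap_when[k]);
  }
  snl.attr("names") = snn;

  return List::create(
      _["fractions"] = frac, _["grid"] = dump_grid(s, L),
      _["snapshots"] = snl,
      _["imposed"] = collect_ledger ? imposed : IntegerMatrix(0, 16),
      _["received"] = collect_ledger ? received : IntegerMatrix(0, 16),
      _["absorbed"] = absorbed);
}
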