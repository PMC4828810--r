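// Minimum-free-energy RNA secondary structure by Zuker-style dynamic
// programming over the nearest-neighbor model supplied from R (see
// rna_energy_params()). Energies are handled as integer tenths of kcal/mol
// so results match the R loop-decomposition evaluator exactly.
//
// Recursions: V(i,j) = best energy with (i,j) paired (hairpin | stacked or
// interior loop bounded by max_interior unpaired | multibranch); WM = at
// least one branch in a multiloop context, WM2 = at least two; W = external.
// Traceback prefers paired/stacked options at the leftmost position among
// co-optimals, giving a deterministic, pairing-rich representative.

#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static const int INF = 100000000;

static inline int pair_idx(char a, char b) {
  // order must match PAIR_LEVELS in R: CG GC AU UA GU UG
  if (a == 'C' && b == 'G') return 0;
  if (a == 'G' && b == 'C') return 1;
  if (a == 'A' && b == 'U') return 2;
  if (a == 'U' && b == 'A') return 3;
  if (a == 'G' && b == 'U') return 4;
  if (a == 'U' && b == 'G') return 5;
  return -1;
}

struct FoldCtx {
  int n;
  std::vector<int> pidx;        // n*n pair index or -1
  std::vector<int> V, WM, WM2;  // n*n energies
  std::vector<int> W;           // external
  std::vector<int> H, B, I;     // loop penalties by size (1-based size -> [size-1])
  int st[6][6];
  int asym_coef10, asym_max10, a10, b10, c10;
  int min_hairpin, max_interior;

  int at(const std::vector<int>& M, int i, int j) const { return M[i * n + j]; }

  int loop_cost(int i, int j, int k, int l) const {
    // cost of the interior loop/stack between outer pair (i,j), inner (k,l)
    int n1 = k - i - 1, n2 = j - l - 1;
    int pij = pidx[i * n + j], pkl = pidx[k * n + l];
    if (n1 == 0 && n2 == 0) return st[pij][pkl];
    if (n1 == 0 || n2 == 0) {
      int nb = n1 + n2;
      if (nb > (int)B.size()) return INF;
      int e = B[nb - 1];
      if (e >= INF) return INF;
      if (nb == 1) e += st[pij][pkl];
      return e;
    }
    int nb = n1 + n2;
    if (nb > (int)I.size()) return INF;
    int e = I[nb - 1];
    if (e >= INF) return INF;
    int asym = asym_coef10 * std::abs(n1 - n2);
    if (asym > asym_max10) asym = asym_max10;
    return e + asym;
  }
};

// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(std::string seq, NumericMatrix stack, NumericVector hairpin,
             NumericVector bulge, NumericVector internal_loop,
             double asym_coef, double asym_max, double ml_init,
             double ml_branch, double ml_unpaired,
             int min_hairpin, int max_interior) {
  int n = seq.size();
  FoldCtx c;
  c.n = n;
  c.min_hairpin = min_hairpin;
  c.max_interior = max_interior;
  c.asym_coef10 = (int)std::lround(asym_coef * 10);
  c.asym_max10 = (int)std::lround(asym_max * 10);
  c.a10 = (int)std::lround(ml_init * 10);
  c.b10 = (int)std::lround(ml_branch * 10);
  c.c10 = (int)std::lround(ml_unpaired * 10);
  for (int p = 0; p < 6; ++p)
    for (int q = 0; q < 6; ++q)
      c.st[p][q] = (int)std::lround(stack(p, q) * 10);
  auto pack = [](NumericVector v, std::vector<int>& out) {
    out.resize(v.size());
    for (int i = 0; i < v.size(); ++i)
      out[i] = R_finite(v[i]) ? (int)std::lround(v[i] * 10) : INF;
  };
  pack(hairpin, c.H);
  pack(bulge, c.B);
  pack(internal_loop, c.I);

  c.pidx.assign((size_t)n * n, -1);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      c.pidx[i * n + j] = pair_idx(seq[i], seq[j]);

  c.V.assign((size_t)n * n, INF);
  c.WM.assign((size_t)n * n, INF);
  c.WM2.assign((size_t)n * n, INF);

  for (int i = n - 1; i >= 0; --i) {
    for (int j = i; j < n; ++j) {
      if (j == i) continue;   // V/WM/WM2 stay INF: no pair, no branch fits
      // --- V ---
      int best = INF;
      if (c.pidx[i * n + j] >= 0 && j - i - 1 >= min_hairpin) {
        if (j - i - 1 <= (int)c.H.size()) {
          int h = c.H[j - i - 2];
          if (h < INF) best = h;
        }
        // stack / bulge / interior
        for (int n1 = 0; n1 <= max_interior; ++n1) {
          int k = i + 1 + n1;
          if (k >= j) break;
          for (int n2 = 0; n2 <= max_interior - n1; ++n2) {
            int l = j - 1 - n2;
            if (l <= k) break;
            int v = c.V[k * n + l];
            if (v >= INF) continue;
            int lc = c.loop_cost(i, j, k, l);
            if (lc >= INF) continue;
            if (v + lc < best) best = v + lc;
          }
        }
        // multibranch
        int wm2 = c.WM2[(i + 1) * n + (j - 1)];
        if (wm2 < INF && c.a10 + c.b10 + wm2 < best)
          best = c.a10 + c.b10 + wm2;
      }
      c.V[i * n + j] = best;

      // --- WM / WM2 ---
      int wm = INF, wm2 = INF;
      if (c.V[i * n + j] < INF) wm = c.V[i * n + j] + c.b10;
      if (c.WM[i * n + (j - 1)] < INF)
        wm = std::min(wm, c.WM[i * n + (j - 1)] + c.c10);
      if (c.WM[(i + 1) * n + j] < INF)
        wm = std::min(wm, c.WM[(i + 1) * n + j] + c.c10);
      for (int k = i + 1; k <= j; ++k) {
        int left = c.WM[i * n + (k - 1)];
        int v = c.V[k * n + j];
        if (left < INF && v < INF) {
          wm = std::min(wm, left + v + c.b10);
          wm2 = std::min(wm2, left + v + c.b10);
        }
      }
      if (j > i && c.WM2[i * n + (j - 1)] < INF)
        wm2 = std::min(wm2, c.WM2[i * n + (j - 1)] + c.c10);
      c.WM[i * n + j] = wm;
      c.WM2[i * n + j] = wm2;
    }
  }

  // external
  c.W.assign(n, 0);
  for (int j = 0; j < n; ++j) {
    int best = (j > 0) ? c.W[j - 1] : 0;
    for (int i = 0; i <= j; ++i) {
      int v = c.V[i * n + j];
      if (v >= INF) continue;
      int left = (i > 0) ? c.W[i - 1] : 0;
      if (left + v < best) best = left + v;
    }
    c.W[j] = best;
  }

  // ---- traceback ----
  std::string db(n, '.');
  struct Seg { int i, j, mode; };     // mode: 1 = V, 2 = WM, 3 = WM2
  std::vector<Seg> stk;

  // external region [0, j]
  {
    int j = n - 1;
    while (j >= 0) {
      int target = c.W[j];
      bool advanced = false;
      for (int i = 0; i <= j; ++i) {   // leftmost pairing preferred
        int v = c.V[i * n + j];
        if (v >= INF) continue;
        int left = (i > 0) ? c.W[i - 1] : 0;
        if (left + v == target) {
          stk.push_back({i, j, 1});
          j = i - 1;
          advanced = true;
          break;
        }
      }
      if (!advanced) --j;              // j unpaired
    }
  }

  while (!stk.empty()) {
    Seg s = stk.back();
    stk.pop_back();
    int i = s.i, j = s.j;
    if (s.mode == 1) {
      db[i] = '('; db[j] = ')';
      int target = c.V[i * n + j];
      bool done = false;
      // interior/stack first (pairing-rich), then multibranch, then hairpin
      for (int n1 = 0; n1 <= c.max_interior && !done; ++n1) {
        int k = i + 1 + n1;
        if (k >= j) break;
        for (int n2 = 0; n2 <= c.max_interior - n1; ++n2) {
          int l = j - 1 - n2;
          if (l <= k) break;
          int v = c.V[k * n + l];
          if (v >= INF) continue;
          int lc = c.loop_cost(i, j, k, l);
          if (lc < INF && v + lc == target) {
            stk.push_back({k, l, 1});
            done = true;
            break;
          }
        }
      }
      if (!done) {
        int wm2 = c.WM2[(i + 1) * n + (j - 1)];
        if (wm2 < INF && c.a10 + c.b10 + wm2 == target) {
          stk.push_back({i + 1, j - 1, 3});
          done = true;
        }
      }
      // else: hairpin loop, nothing to trace
    } else if (s.mode == 2) {
      int target = c.WM[i * n + j];
      if (c.V[i * n + j] < INF && c.V[i * n + j] + c.b10 == target) {
        stk.push_back({i, j, 1});
        continue;
      }
      bool done = false;
      for (int k = i + 1; k <= j && !done; ++k) {
        int left = c.WM[i * n + (k - 1)];
        int v = c.V[k * n + j];
        if (left < INF && v < INF && left + v + c.b10 == target) {
          stk.push_back({i, k - 1, 2});
          stk.push_back({k, j, 1});
          done = true;
        }
      }
      if (done) continue;
      if (j > i && c.WM[i * n + (j - 1)] < INF &&
          c.WM[i * n + (j - 1)] + c.c10 == target) {
        stk.push_back({i, j - 1, 2});
        continue;
      }
      if (j > i && c.WM[(i + 1) * n + j] < INF &&
          c.WM[(i + 1) * n + j] + c.c10 == target) {
        stk.push_back({i + 1, j, 2});
        continue;
      }
      // single unpaired stretch: nothing to trace
    } else {  // WM2
      int target = c.WM2[i * n + j];
      bool done = false;
      for (int k = i + 1; k <= j && !done; ++k) {
        int left = c.WM[i * n + (k - 1)];
        int v = c.V[k * n + j];
        if (left < INF && v < INF && left + v + c.b10 == target) {
          stk.push_back({i, k - 1, 2});
          stk.push_back({k, j, 1});
          done = true;
        }
      }
      if (done) continue;
      if (j > i && c.WM2[i * n + (j - 1)] < INF &&
          c.WM2[i * n + (j - 1)] + c.c10 == target) {
        stk.push_back({i, j - 1, 3});
      }
    }
  }

  return List::create(_["structure"] = db,
                      _["mfe"] = c.W[n - 1] / 10.0);
}
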