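#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Simplified nearest-neighbour energy model (kcal/mol).
// Stabilising energy comes only from stacked pairs; the stack contribution is
// attributed to the outer pair of each stacked duo:
//   GC or CG -3.0, AU or UA -2.0, GU or UG -1.0
// Loop penalties: hairpin +4.0 (>= 3 unpaired); internal loop / bulge
// +3.0 + 0.5 per unpaired nt; a multibranch loop is charged like an internal
// loop (+3.0 + 0.5 per unpaired nt in the loop). Exterior bases are free.
// Internal loops / bulges larger than MAXLOOP unpaired nt total are
// disallowed (part of the model definition, as in standard MFE folders).

static const double STACK_GC = -3.0;
static const double STACK_AU = -2.0;
static const double STACK_GU = -1.0;
static const double HAIRPIN_PENALTY = 4.0;
static const double LOOP_OPEN = 3.0;
static const double LOOP_PER_NT = 0.5;
static const double MULTI_OPEN = 3.0;
static const int MIN_HAIRPIN = 3;
static const int MAXLOOP = 15;
static const double INF_E = 1e9;

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

static inline double stack_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return STACK_GC;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return STACK_AU;
  return STACK_GU;
}

struct FoldDP {
  int n;
  std::string s;
  std::vector<std::vector<double> > V, WM, WM2;
  std::vector<double> W;

  explicit FoldDP(const std::string &seq) : n((int)seq.size()), s(seq) {
    V.assign(n, std::vector<double>(n, INF_E));
    WM.assign(n, std::vector<double>(n, INF_E));
    WM2.assign(n, std::vector<double>(n, INF_E));
    W.assign(n + 1, 0.0);
    fill();
  }

  void fill() {
    for (int span = MIN_HAIRPIN + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        if (can_pair(s[i], s[j])) V[i][j] = closed(i, j);
        // WM: segment holding >= 1 branch, 0.5 per unpaired nt
        double best = INF_E;
        if (V[i][j] < best) best = V[i][j];
        if (i + 1 <= j && WM[i + 1][j] < INF_E / 2) best = std::min(best, WM[i + 1][j] + LOOP_PER_NT);
        if (j - 1 >= i && WM[i][j - 1] < INF_E / 2) best = std::min(best, WM[i][j - 1] + LOOP_PER_NT);
        double best2 = INF_E;
        for (int k = i + 1; k <= j; ++k) {
          if (WM[i][k - 1] < INF_E / 2 && WM[k][j] < INF_E / 2) {
            double e = WM[i][k - 1] + WM[k][j];
            if (e < best2) best2 = e;
            if (e < best) best = e;
          }
        }
        WM[i][j] = best;
        WM2[i][j] = best2;
      }
      // short spans: WM for spans < MIN_HAIRPIN+1 stay INF (no branch fits)
    }
    for (int j = 1; j <= n; ++j) {
      W[j] = W[j - 1];
      for (int k = 1; k <= j; ++k) {
        double v = V[k - 1][j - 1];
        if (v < INF_E / 2 && W[k - 1] + v < W[j]) W[j] = W[k - 1] + v;
      }
    }
  }

  double closed(int i, int j) {
    double best = INF_E;
    int loop = j - i - 1;
    if (loop >= MIN_HAIRPIN) best = HAIRPIN_PENALTY;  // hairpin loop
    // stack
    if (i + 1 < j - 1 && V[i + 1][j - 1] < INF_E / 2)
      best = std::min(best, stack_energy(s[i], s[j]) + V[i + 1][j - 1]);
    // internal loop / bulge (>= 1 unpaired nt between the pairs)
    for (int k = i + 1; k < j - 1; ++k) {
      int left = k - i - 1;
      if (left > MAXLOOP) break;
      int lmin = j - 1 - (MAXLOOP - left);
      if (lmin < k + 1) lmin = k + 1;
      for (int l = j - 1; l >= lmin; --l) {
        int right = j - l - 1;
        int unp = left + right;
        if (unp == 0) continue;  // that's the stack case
        if (V[k][l] < INF_E / 2) {
          double e = LOOP_OPEN + LOOP_PER_NT * unp + V[k][l];
          if (e < best) best = e;
        }
      }
    }
    // multibranch: >= 2 branches inside
    if (i + 1 <= j - 1 && WM2[i + 1][j - 1] < INF_E / 2)
      best = std::min(best, MULTI_OPEN + WM2[i + 1][j - 1]);
    return best;
  }

  // ---- traceback -------------------------------------------------------
  // Ties are broken deterministically: pairing is preferred over leaving a
  // base unpaired, stacking over opening a loop, and 5'-most inner pairs win.
  std::vector<int> pair_of;

  void traceback() {
    pair_of.assign(n, -1);
    trace_W(n);
  }

  void trace_W(int j) {
    const double eps = 1e-9;
    if (j == 0) return;
    // prefer a pair ending at j (5'-most k first)
    for (int k = 1; k <= j; ++k) {
      double v = V[k - 1][j - 1];
      if (v < INF_E / 2 && std::fabs(W[k - 1] + v - W[j]) < eps) {
        trace_V(k - 1, j - 1);
        trace_W(k - 1);
        return;
      }
    }
    trace_W(j - 1);
  }

  void trace_V(int i, int j) {
    const double eps = 1e-9;
    pair_of[i] = j; pair_of[j] = i;
    double target = V[i][j];
    // stack first
    if (i + 1 < j - 1 && V[i + 1][j - 1] < INF_E / 2 &&
        std::fabs(stack_energy(s[i], s[j]) + V[i + 1][j - 1] - target) < eps) {
      trace_V(i + 1, j - 1);
      return;
    }
    // internal loops, 5'-most inner pair first, smallest loop first
    for (int k = i + 1; k < j - 1 && k - i - 1 <= MAXLOOP; ++k) {
      for (int l = j - 1; l > k; --l) {
        int unp = (k - i - 1) + (j - l - 1);
        if (unp == 0 || unp > MAXLOOP) continue;
        if (V[k][l] < INF_E / 2 &&
            std::fabs(LOOP_OPEN + LOOP_PER_NT * unp + V[k][l] - target) < eps) {
          trace_V(k, l);
          return;
        }
      }
    }
    // multibranch
    if (i + 1 <= j - 1 && WM2[i + 1][j - 1] < INF_E / 2 &&
        std::fabs(MULTI_OPEN + WM2[i + 1][j - 1] - target) < eps) {
      trace_WM2(i + 1, j - 1);
      return;
    }
    // hairpin: nothing further to trace
  }

  void trace_WM2(int i, int j) {
    const double eps = 1e-9;
    for (int k = i + 1; k <= j; ++k) {
      if (WM[i][k - 1] < INF_E / 2 && WM[k][j] < INF_E / 2 &&
          std::fabs(WM[i][k - 1] + WM[k][j] - WM2[i][j]) < eps) {
        trace_WM(i, k - 1);
        trace_WM(k, j);
        return;
      }
    }
  }

  void trace_WM(int i, int j) {
    const double eps = 1e-9;
    double target = WM[i][j];
    if (V[i][j] < INF_E / 2 && std::fabs(V[i][j] - target) < eps) {
      trace_V(i, j);
      return;
    }
    for (int k = i + 1; k <= j; ++k) {
      if (WM[i][k - 1] < INF_E / 2 && WM[k][j] < INF_E / 2 &&
          std::fabs(WM[i][k - 1] + WM[k][j] - target) < eps) {
        trace_WM(i, k - 1);
        trace_WM(k, j);
        return;
      }
    }
    if (i + 1 <= j && WM[i + 1][j] < INF_E / 2 &&
        std::fabs(WM[i + 1][j] + LOOP_PER_NT - target) < eps) {
      trace_WM(i + 1, j);
      return;
    }
    if (j - 1 >= i && WM[i][j - 1] < INF_E / 2 &&
        std::fabs(WM[i][j - 1] + LOOP_PER_NT - target) < eps) {
      trace_WM(i, j - 1);
      return;
    }
  }
};

// [[Rcpp::export(name = ".fold_nn")]]
List fold_nn(std::string seq) {
  int n = (int)seq.size();
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'U')
      stop("non-ACGU symbol '%s' at offset %d", std::string(1, c).c_str(), i + 1);
  }
  if (n == 0) return List::create(_["structure"] = "", _["energy"] = 0.0,
                                  _["pairs"] = IntegerVector(0));
  FoldDP dp(seq);
  dp.traceback();
  std::string db(n, '.');
  IntegerVector pairs(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (dp.pair_of[i] >= 0) {
      db[i] = (dp.pair_of[i] > i) ? '(' : ')';
      pairs[i] = dp.pair_of[i] + 1;  // 1-based partner
    }
  }
  return List::create(_["structure"] = db, _["energy"] = dp.W[n],
                      _["pairs"] = pairs);
}

// Exact score of one 20-21 nt tag against every position of every transcript
// is done in R via Biostrings; no C++ needed there.
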