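#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Minimum-free-energy folding of a single RNA strand under a simple
// stacking-energy model: Watson-Crick + G.U pairs, minimum hairpin loop of
// 3 nt, and an energy contribution for each pair (i,j) whose enclosed
// neighbours (i+1,j-1) are also paired to each other (GC -3, AU -2, GU -1
// per such stacked pair; the outermost pair of a helix contributes 0).
// Nested structures only (no pseudoknots). Ties broken toward the
// 5'-most opening pair during traceback.

static const double INF = 1e9;
static const int MIN_LOOP = 3;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

// pair energy; INF if the two bases cannot pair
static inline double pair_energy(int a, int b) {
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return -2.0; // A-U
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return -3.0; // G-C
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return -1.0; // G-U
  return INF;
}

struct FoldDP {
  int n;
  std::vector<int> code;
  std::vector<double> V, W; // n x n, row-major

  double &v(int i, int j) { return V[(size_t)i * n + j]; }
  double &w(int i, int j) { return W[(size_t)i * n + j]; }

  bool pairable(int i, int j) const {
    if (j - i - 1 < MIN_LOOP) return false;
    return pair_energy(code[i], code[j]) < INF / 2;
  }

  double estack(int i, int j) const { return pair_energy(code[i], code[j]); }

  void run(const std::string &seq) {
    n = (int)seq.size();
    code.resize(n);
    for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);
    V.assign((size_t)n * n, INF);
    W.assign((size_t)n * n, 0.0);
    for (int len = MIN_LOOP + 2; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        // V(i,j): (i,j) paired
        if (pairable(i, j)) {
          double best = 0.0; // hairpin closes at 0
          double inner = w(i + 1, j - 1);
          if (inner < best) best = inner;
          if (pairable(i + 1, j - 1)) {
            double st = v(i + 1, j - 1) + estack(i, j);
            if (st < best) best = st;
          }
          v(i, j) = best;
        }
        // W(i,j): any structure on [i,j]
        double best = w(i, j - 1); // j unpaired
        for (int k = i; k + MIN_LOOP + 1 <= j; ++k) {
          if (v(k, j) >= INF / 2) continue;
          double cand = (k > i ? w(i, k - 1) : 0.0) + v(k, j);
          if (cand < best) best = cand;
        }
        w(i, j) = best;
      }
    }
  }

  void traceV(int i, int j, std::vector<int> &partner);

  void traceW(int i, int j, std::vector<int> &partner) {
    while (j > i) {
      double target = w(i, j);
      // prefer pairing j with the 5'-most k that achieves the optimum
      int chosen = -1;
      for (int k = i; k + MIN_LOOP + 1 <= j; ++k) {
        if (v(k, j) >= INF / 2) continue;
        double cand = (k > i ? w(i, k - 1) : 0.0) + v(k, j);
        if (cand <= target + 1e-9) { chosen = k; break; }
      }
      if (chosen >= 0) {
        traceV(chosen, j, partner);
        if (chosen == i) return;
        j = chosen - 1;
      } else {
        --j; // j unpaired
      }
    }
  }
};

void FoldDP::traceV(int i, int j, std::vector<int> &partner) {
  partner[i] = j;
  partner[j] = i;
  double target = v(i, j);
  if (pairable(i + 1, j - 1)) {
    double st = v(i + 1, j - 1) + estack(i, j);
    if (st <= target + 1e-9) { traceV(i + 1, j - 1, partner); return; }
  }
  if (j - 1 > i + 1 && w(i + 1, j - 1) <= target + 1e-9) {
    traceW(i + 1, j - 1, partner);
    return;
  }
  // hairpin: nothing inside
}

// [[Rcpp::export(name = ".fold_dp_cpp")]]
List fold_dp_cpp(std::string seq) {
  int n = (int)seq.size();
  for (int i = 0; i < n; ++i) {
    if (base_code(seq[i]) < 0)
      stop("non-RNA character in sequence at position %d", i + 1);
  }
  if (n < 2) {
    return List::create(_["structure"] = std::string(n, '.'),
                        _["mfe"] = 0.0,
                        _["pairs"] = IntegerVector(n, 0));
  }
  FoldDP dp;
  dp.run(seq);
  double mfe = dp.w(0, n - 1);
  std::vector<int> partner(n, -1);
  dp.traceW(0, n - 1, partner);
  std::string db(n, '.');
  IntegerVector pairs(n, 0);
  for (int i = 0; i < n; ++i) {
    if (partner[i] >= 0) {
      pairs[i] = partner[i] + 1; // 1-based partner, 0 = unpaired
      db[i] = (partner[i] > i) ? '(' : ')';
    }
  }
  return List::create(_["structure"] = db, _["mfe"] = mfe, _["pairs"] = pairs);
}

// MFE of each k-mer tiling the sequence, assigned to the k-mer's centre
// position (0-based offset k/2 - 1 for even k, k/2 for odd). Positions
// without a complete window are NA.
// [[Rcpp::export(name = ".tile_fold_cpp")]]
NumericVector tile_fold_cpp(std::string seq, int k) {
  int n = (int)seq.size();
  NumericVector out(n, NA_REAL);
  if (n < k) return out;
  int centre = (k % 2 == 0) ? k / 2 - 1 : k / 2;
  FoldDP dp;
  for (int i = 0; i + k <= n; ++i) {
    std::string sub = seq.substr(i, k);
    bool ok = true;
    for (int p = 0; p < k; ++p)
      if (base_code(sub[p]) < 0) { ok = false; break; }
    if (!ok) continue; // N or other ambiguity: leave NA
    dp.run(sub);
    out[i + centre] = dp.w(0, k - 1);
  }
  return out;
}
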