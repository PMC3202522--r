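#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Boltzmann-weighted partition function over nested secondary structures with
// a simple per-pair energy model (GC/AU/GU, kcal/mol) and a minimum hairpin
// loop. Bases are encoded 0=A, 1=C, 2=G, 3=U, 4=N; N never pairs.
//
// Per-position unpaired probabilities are computed exactly as
// Z(position forced unpaired) / Z, each Z from the O(n^3) inside recursion
//   Q(i,j) = Q(i,j-1) + sum_k Q(i,k-1) * w(k,j) * Q(k+1,j-1)
// conditioning on the pairing partner of j. The per-position recomputation is
// O(n^4) overall, exact in double precision for the window sizes used
// (default 80 nt; pair weights stay far below double overflow for windows of
// a few hundred nt).

static inline double pair_weight(int a, int b, double wgc, double wau,
                                 double wgu) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return wgc;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return wau;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return wgu;
  return 0.0;
}

// Inside partition function over the whole sequence, with position `forced`
// (0-based; -1 for none) constrained to be unpaired.
static double inside_Z(const std::vector<int> &s, int n, int forced,
                       double wgc, double wau, double wgu, int minloop) {
  std::vector<double> Q((size_t)n * n, 0.0);
  const int N = n;
  for (int len = 1; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double q = (j - 1 >= i) ? Q[(size_t)i * N + (j - 1)] : 1.0; // j unpaired
      if (j != forced) {
        for (int k = i; k <= j - minloop - 1; ++k) {
          if (k == forced) continue;
          double w = pair_weight(s[k], s[j], wgc, wau, wgu);
          if (w == 0.0) continue;
          double left = (k - 1 >= i) ? Q[(size_t)i * N + (k - 1)] : 1.0;
          double inner = (k + 1 <= j - 1) ? Q[(size_t)(k + 1) * N + (j - 1)] : 1.0;
          q += left * w * inner;
        }
      }
      Q[(size_t)i * N + j] = q;
    }
  }
  return Q[(size_t)0 * N + (n - 1)];
}

// [[Rcpp::export]]
NumericVector unpaired_probs_cpp(IntegerVector seq, double wgc, double wau,
                                 double wgu, int min_loop) {
  int n = seq.size();
  NumericVector p(n);
  if (n == 0) return p;
  std::vector<int> s(seq.begin(), seq.end());
  double Z = inside_Z(s, n, -1, wgc, wau, wgu, min_loop);
  for (int i = 0; i < n; ++i) {
    // a position with no admissible partner is unpaired in every structure
    bool pairable = false;
    for (int j = 0; j < n && !pairable; ++j) {
      if (std::abs(j - i) >= min_loop + 1 &&
          pair_weight(s[i], s[j], wgc, wau, wgu) > 0.0) {
        pairable = true;
      }
    }
    p[i] = pairable ? inside_Z(s, n, i, wgc, wau, wgu, min_loop) / Z : 1.0;
  }
  return p;
}
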