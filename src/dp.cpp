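#include <Rcpp.h>
using namespace Rcpp;

// Block-constrained alignment DP.
//
// Maximises F = sum_{(i,j) in pi} S(i,j) - penalty * ((L1-Na) + (L2-Na))
// over order-preserving one-to-one matchings in which every matched site
// lies in a diagonal run of length >= min_block.  Internally works on the
// per-pair gain G = S + 2*penalty: F = sum(G over pi) - penalty*(L1+L2).
//
// Ties on the objective prefer more matched pairs; remaining ties are
// resolved by a fixed candidate order (skip-row, skip-col, shortest
// block), making the output deterministic.
//
// [[Rcpp::export]]
List dp_align_cpp(NumericMatrix S, double penalty, int min_block) {
  const int n1 = S.nrow(), n2 = S.ncol();
  const int R = n1 + 1, C = n2 + 1;

  std::vector<double> best((size_t)R * C, 0.0);
  std::vector<int> np((size_t)R * C, 0);
  std::vector<signed char> choice((size_t)R * C, 0); // 0 none,1 up,2 left,3 block
  std::vector<int> blen((size_t)R * C, 0);

  auto at = [C](int i, int j) { return (size_t)i * C + j; };

  const double twop = 2.0 * penalty;

  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      double bv = best[at(i - 1, j)];
      int bnp = np[at(i - 1, j)];
      signed char bch = 1;
      int bbl = 0;

      double lv = best[at(i, j - 1)];
      int lnp = np[at(i, j - 1)];
      if (lv > bv || (lv == bv && lnp > bnp)) {
        bv = lv; bnp = lnp; bch = 2; bbl = 0;
      }

      const int maxk = std::min(i, j);
      double s = 0.0;
      for (int k = 1; k <= maxk; ++k) {
        s += S(i - k, j - k) + twop; // 0-based access to cell (i-k+1, j-k+1)
        if (k >= min_block) {
          double v = s + best[at(i - k, j - k)];
          int vn = np[at(i - k, j - k)] + k;
          if (v > bv || (v == bv && vn > bnp)) {
            bv = v; bnp = vn; bch = 3; bbl = k;
          }
        }
      }
      best[at(i, j)] = bv;
      np[at(i, j)] = bnp;
      choice[at(i, j)] = bch;
      blen[at(i, j)] = bbl;
    }
  }

  // backtrack
  std::vector<int> ai, bj;
  int i = n1, j = n2;
  while (i > 0 && j > 0) {
    signed char ch = choice[at(i, j)];
    if (ch == 1) --i;
    else if (ch == 2) --j;
    else if (ch == 3) {
      int k = blen[at(i, j)];
      for (int t = 0; t < k; ++t) { ai.push_back(i - t); bj.push_back(j - t); }
      i -= k; j -= k;
    } else break;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj.begin(), bj.end());

  IntegerMatrix pairs(ai.size(), 2);
  for (size_t t = 0; t < ai.size(); ++t) {
    pairs(t, 0) = ai[t];
    pairs(t, 1) = bj[t];
  }
  const double gain = (n1 > 0 && n2 > 0) ? best[at(n1, n2)] : 0.0;
  return List::create(_["pairs"] = pairs,
                      _["gain"] = gain,
                      _["objective"] = gain - penalty * (n1 + n2));
}
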