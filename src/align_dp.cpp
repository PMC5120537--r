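#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch style) alignment over an arbitrary residue-pair
// score matrix with a linear gap penalty. Scores are expected to be
// non-negative (cells are typically max(0, d0 - d_ij)); gaps, including end
// gaps, cost `gap` each. Ties are broken deterministically: diagonal move
// first, then the move consuming a residue of chain A, then chain B.
//
// Returns a k x 2 integer matrix of 1-based (pos_a, pos_b) pairs, strictly
// increasing in both columns.
// [[Rcpp::export]]
IntegerMatrix nw_align_cpp(NumericMatrix S, double gap) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix F(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1); // 1 = diag, 2 = up (gap in B), 3 = left (gap in A)

  for (int i = 1; i <= n; ++i) { F(i, 0) = -gap * i; P(i, 0) = 2; }
  for (int j = 1; j <= m; ++j) { F(0, j) = -gap * j; P(0, j) = 3; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = F(i - 1, j - 1) + S(i - 1, j - 1);
      double u = F(i - 1, j) - gap;
      double l = F(i, j - 1) - gap;
      double best = d; int ptr = 1;
      if (u > best) { best = u; ptr = 2; }
      if (l > best) { best = l; ptr = 3; }
      F(i, j) = best;
      P(i, j) = ptr;
    }
  }

  // traceback
  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int ptr = P(i, j);
    if (ptr == 1) { pa.push_back(i); pb.push_back(j); --i; --j; }
    else if (ptr == 2) { --i; }
    else { --j; }
  }
  const int k = pa.size();
  IntegerMatrix out(k, 2);
  for (int r = 0; r < k; ++r) {
    out(r, 0) = pa[k - 1 - r];
    out(r, 1) = pb[k - 1 - r];
  }
  return out;
}
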