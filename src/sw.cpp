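#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps on pre-encoded
// residue index vectors (0-based rows/cols of the substitution matrix).
// A gap of length L costs gap_open + L * gap_extend (BLAST convention:
// "existence" + per-residue extension). Score floors at 0 (the empty
// local alignment); spans are 1-based and NA when the best score is 0.
// [[Rcpp::export]]
List sw_align_idx(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  const double NEG = -1e30;
  if (m == 0 || n == 0) {
    return List::create(_["score"] = 0.0,
                        _["a_start"] = NA_INTEGER, _["a_end"] = NA_INTEGER,
                        _["b_start"] = NA_INTEGER, _["b_end"] = NA_INTEGER);
  }
  NumericMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  for (int j = 0; j <= n; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= m; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }
  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E(i, j) = std::max(H(i, j - 1) - gap_open - gap_extend,
                         E(i, j - 1) - gap_extend);
      F(i, j) = std::max(H(i - 1, j) - gap_open - gap_extend,
                         F(i - 1, j) - gap_extend);
      double diag = H(i - 1, j - 1) + S(a[i - 1], b[j - 1]);
      double h = std::max(0.0, std::max(diag, std::max(E(i, j), F(i, j))));
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["a_start"] = NA_INTEGER, _["a_end"] = NA_INTEGER,
                        _["b_start"] = NA_INTEGER, _["b_end"] = NA_INTEGER);
  }
  // traceback through the three-state DP to find the alignment start
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E (gap in a), 2 = F (gap in b)
  const double eps = 1e-9;
  while (true) {
    if (state == 0) {
      if (H(i, j) <= eps) break;
      double diag = H(i - 1, j - 1) + S(a[i - 1], b[j - 1]);
      if (std::abs(H(i, j) - diag) < eps) { --i; --j; }
      else if (std::abs(H(i, j) - E(i, j)) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      if (std::abs(E(i, j) - (H(i, j - 1) - gap_open - gap_extend)) < eps) {
        --j; state = 0;
      } else { --j; }
    } else {
      if (std::abs(F(i, j) - (H(i - 1, j) - gap_open - gap_extend)) < eps) {
        --i; state = 0;
      } else { --i; }
    }
  }
  return List::create(_["score"] = best,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj);
}
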