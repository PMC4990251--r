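#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh). A gap of length L
// costs gap_open + gap_extend * L. Sequences arrive as 1-based indices into
// the substitution matrix. Traceback is deterministic: ties prefer the
// diagonal move, then the up move (gap in target), then the left move
// (gap in query); the best cell is the first maximum in row-major order
// (smallest query end, then smallest target end). Returns the raw score, the
// 1-based inclusive end coordinates and the operation string from alignment
// start to end ('D' diagonal, 'U' up, 'L' left).
// [[Rcpp::export(name = ".sw_align_c")]]
List sw_align_c(IntegerVector a, IntegerVector b, NumericMatrix S,
                double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  const double NEG = -1e30;
  const double gi = gap_open + gap_extend;  // cost of opening (first residue)
  NumericMatrix H(m + 1, n + 1), E(m + 1, n + 1), F(m + 1, n + 1);
  for (int j = 0; j <= n; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= m; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E(i, j) = std::max(H(i - 1, j) - gi, E(i - 1, j) - gap_extend);
      F(i, j) = std::max(H(i, j - 1) - gi, F(i, j - 1) - gap_extend);
      double diag = H(i - 1, j - 1) + S(a[i - 1] - 1, b[j - 1] - 1);
      double h = 0.0;
      if (diag > h) h = diag;
      if (E(i, j) > h) h = E(i, j);
      if (F(i, j) > h) h = F(i, j);
      H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["q_end"] = 0, _["t_end"] = 0,
                        _["ops"] = "");
  }
  // traceback with recomputation; state 0 = H, 1 = E (up), 2 = F (left)
  std::string ops;
  int i = bi, j = bj, state = 0;
  while (true) {
    if (state == 0) {
      if (H(i, j) == 0.0) break;
      double diag = H(i - 1, j - 1) + S(a[i - 1] - 1, b[j - 1] - 1);
      if (H(i, j) == diag) {
        ops.push_back('D'); --i; --j;
      } else if (H(i, j) == E(i, j)) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ops.push_back('U');
      // prefer closing the gap (return to H) on ties
      if (E(i, j) == H(i - 1, j) - gi) { --i; state = 0; }
      else { --i; }
    } else {
      ops.push_back('L');
      if (F(i, j) == H(i, j - 1) - gi) { --j; state = 0; }
      else { --j; }
    }
    if (i == 0 || j == 0) break;
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["q_end"] = bi, _["t_end"] = bj,
                      _["ops"] = ops);
}
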