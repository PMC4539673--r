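// Global profile-profile alignment with affine gap costs
// (Needleman-Wunsch / Gotoh). The column-pair substitution scores are
// precomputed in R; ties are broken deterministically in the order
// match > gap-in-B > gap-in-A so the progressive aligner is reproducible.
#include <Rcpp.h>
using namespace Rcpp;

// moves: 1 = consume a column from both profiles, 2 = column from A only
// (gap in B), 3 = column from B only (gap in A)
// [[Rcpp::export(name = ".profileAlignCpp")]]
IntegerVector profileAlignCpp(NumericMatrix score, double gapOpen,
                              double gapExtend) {
  const int n = score.nrow(), m = score.ncol();
  const double NEG = -1e30;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);

  M(0, 0) = 0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = gapOpen + gapExtend * (i - 1);
    tX(i, 0) = 2;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = gapOpen + gapExtend * (j - 1);
    tY(0, j) = 3;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = score(i - 1, j - 1);
      // M: best ending in a match column
      double a = M(i - 1, j - 1), b = X(i - 1, j - 1), c = Y(i - 1, j - 1);
      if (a >= b && a >= c) { M(i, j) = a + s; tM(i, j) = 1; }
      else if (b >= c)      { M(i, j) = b + s; tM(i, j) = 2; }
      else                  { M(i, j) = c + s; tM(i, j) = 3; }
      // X: gap in B (consume A)
      a = M(i - 1, j) + gapOpen; b = X(i - 1, j) + gapExtend;
      if (a >= b) { X(i, j) = a; tX(i, j) = 1; } else { X(i, j) = b; tX(i, j) = 2; }
      // Y: gap in A (consume B)
      a = M(i, j - 1) + gapOpen; c = Y(i, j - 1) + gapExtend;
      if (a >= c) { Y(i, j) = a; tY(i, j) = 1; } else { Y(i, j) = c; tY(i, j) = 3; }
    }
  }

  int state;
  double a = M(n, m), b = X(n, m), c = Y(n, m);
  if (a >= b && a >= c) state = 1; else if (b >= c) state = 2; else state = 3;

  std::vector<int> moves;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 1) {
      int prev = tM(i, j);
      moves.push_back(1); --i; --j; state = prev;
    } else if (state == 2) {
      int prev = tX(i, j);
      moves.push_back(2); --i; state = (prev == 1) ? 1 : 2;
    } else {
      int prev = tY(i, j);
      moves.push_back(3); --j; state = (prev == 1) ? 1 : 3;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return wrap(moves);
}
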