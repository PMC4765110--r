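#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh, three layers) on a precomputed
// column-vs-column score matrix S (n x m).  Rows of S index columns of
// profile A, columns of S index columns of profile B, so the same kernel
// serves sequence-sequence, sequence-profile and profile-profile steps.
//
// Gap cost convention: a maximal gap run of length k costs
// gapOpen + (k - 1) * gapExtend, with gapOpen <= gapExtend < 0.
// Adjacent gap runs in opposite rows are charged separately (the Y->X and
// X->Y transitions pay gapOpen again).
//
// Tie-breaking, both in the recurrences and in the traceback, prefers
// diagonal (match), then up (gap in B), then left (gap in A), so results
// are deterministic across platforms.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".affineAlign")]]
List affineAlign(NumericMatrix S, double gapOpen, double gapExtend) {
  const int n = S.nrow(), m = S.ncol();
  if (n < 1 || m < 1) stop("empty profile passed to alignment kernel");

  // layer codes: 0 = M (diagonal), 1 = X (up, consumes A), 2 = Y (left)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = gapOpen + (i - 1) * gapExtend;
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = gapOpen + (j - 1) * gapExtend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int dij = at(i - 1, j - 1), uij = at(i - 1, j), lij = at(i, j - 1);
      // M: best of the three layers at (i-1, j-1), tie pref M > X > Y
      double best = M[dij];
      if (X[dij] > best) best = X[dij];
      if (Y[dij] > best) best = Y[dij];
      M[at(i, j)] = (best == NEG_INF) ? NEG_INF : best + S(i - 1, j - 1);
      // X: consume a column of A against a gap
      double x = M[uij] + gapOpen;
      if (X[uij] + gapExtend > x) x = X[uij] + gapExtend;
      if (Y[uij] + gapOpen > x) x = Y[uij] + gapOpen;
      X[at(i, j)] = x;
      // Y: consume a column of B against a gap
      double y = M[lij] + gapOpen;
      if (X[lij] + gapOpen > y) y = X[lij] + gapOpen;
      if (Y[lij] + gapExtend > y) y = Y[lij] + gapExtend;
      Y[at(i, j)] = y;
    }
  }

  // final state: tie pref M > X > Y
  int state;
  double score = M[at(n, m)];
  state = 0;
  if (X[at(n, m)] > score) { score = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > score) { score = Y[at(n, m)]; state = 2; }

  // traceback
  std::vector<int> ai, bi;
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      const int dij = at(i - 1, j - 1);
      const double tgt = M[at(i, j)] - S(i - 1, j - 1);
      if (std::abs(M[dij] - tgt) < eps) state = 0;
      else if (std::abs(X[dij] - tgt) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      ai.push_back(i); bi.push_back(0);
      if (i == 1 && j == 0) { --i; continue; }
      const int uij = at(i - 1, j);
      const double v = X[at(i, j)];
      if (i > 1 || j > 0) {
        if (std::abs(M[uij] + gapOpen - v) < eps) state = 0;
        else if (std::abs(X[uij] + gapExtend - v) < eps) state = 1;
        else state = 2;
      }
      --i;
    } else {
      ai.push_back(0); bi.push_back(j);
      if (j == 1 && i == 0) { --j; continue; }
      const int lij = at(i, j - 1);
      const double v = Y[at(i, j)];
      if (j > 1 || i > 0) {
        if (std::abs(M[lij] + gapOpen - v) < eps) state = 0;
        else if (std::abs(X[lij] + gapOpen - v) < eps) state = 1;
        else state = 2;
      }
      --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  return List::create(_["score"] = score,
                      _["aIndex"] = wrap(ai),
                      _["bIndex"] = wrap(bi));
}
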