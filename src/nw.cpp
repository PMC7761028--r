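#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment over a precomputed cell-score matrix.
// S(i,j) is the score for pairing row-unit i with column-unit j, so the same
// kernel aligns residue-residue (S = substitution lookups) and
// profile-profile (S = expected substitution score between columns).
// A gap of length L costs gapOpen + (L-1) * gapExtend (both <= 0).
// Traceback is deterministic: on ties diagonal > up (gap in columns) > left.
// [[Rcpp::export(name = ".nwAffine")]]
List nwAffine(NumericMatrix S, double gapOpen, double gapExtend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  // layer 0 = M (diag), 1 = X (up: consume row unit), 2 = Y (left)
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = gapOpen + (i - 1) * gapExtend;
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = gapOpen + (j - 1) * gapExtend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)],
             dY = Y[at(i - 1, j - 1)];
      double best = dM;
      if (dX > best) best = dX;
      if (dY > best) best = dY;
      M[at(i, j)] = best + S(i - 1, j - 1);
      double xo = M[at(i - 1, j)] + gapOpen, xe = X[at(i - 1, j)] + gapExtend;
      X[at(i, j)] = xo >= xe ? xo : xe;
      double yo = M[at(i, j - 1)] + gapOpen, ye = Y[at(i, j - 1)] + gapExtend;
      Y[at(i, j)] = yo >= ye ? yo : ye;
    }
  }
  // final state: prefer M > X > Y on ties
  int state = 0;
  double score = M[at(n, m)];
  if (X[at(n, m)] > score) { score = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > score) { score = Y[at(n, m)]; state = 2; }
  std::vector<int> moves;
  moves.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) stop("traceback error");
      moves.push_back(1);
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)],
             dY = Y[at(i - 1, j - 1)];
      double best = std::max(dM, std::max(dX, dY));
      if (dM >= best) state = 0;
      else if (dX >= best) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      moves.push_back(2);
      if (i == 1 && j == 0) { --i; state = 0; continue; }
      double xo = M[at(i - 1, j)] + gapOpen, xe = X[at(i - 1, j)] + gapExtend;
      state = (xo >= xe) ? 0 : 1;
      --i;
    } else {
      moves.push_back(3);
      if (j == 1 && i == 0) { --j; state = 0; continue; }
      double yo = M[at(i, j - 1)] + gapOpen, ye = Y[at(i, j - 1)] + gapExtend;
      state = (yo >= ye) ? 0 : 2;
      --j;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = score, _["moves"] = wrap(moves));
}
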