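#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise DP over a precomputed cell score matrix S (n x m).
// S[i,j] is the score of pairing element i of A with element j of B, so the
// same engine aligns residues against residues or profile columns against
// profile columns. A gap of length L costs open + L * extend (BLAST-style).
//
// Tie-breaks are fixed for determinism: diagonal (match) > up (gap in B)
// > left (gap in A), both when choosing the best predecessor and when
// choosing the final state.

static const double NEG_INF = -1e300;

// state codes: 0 = M (diagonal), 1 = X (up, A element vs gap),
//              2 = Y (left, gap vs B element)

// [[Rcpp::export(name = ".affine_align_cpp")]]
List affine_align_cpp(NumericMatrix S, double gap_open, double gap_extend,
                      bool local) {
  const int n = S.nrow(), m = S.ncol();
  const double gop = gap_open + gap_extend;  // cost of a length-1 gap
  const double gex = gap_extend;

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix pM(n + 1, m + 1), pX(n + 1, m + 1), pY(n + 1, m + 1);

  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG_INF; }

  M(0, 0) = local ? 0.0 : 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) { X(i, 0) = -(gap_open + i * gex); pX(i, 0) = 1; }
    for (int j = 1; j <= m; ++j) { Y(0, j) = -(gap_open + j * gex); pY(0, j) = 2; }
  }

  double best = 0.0; int bi = 0, bj = 0;  // local-mode best cell

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: from M, X, Y at (i-1, j-1); local mode may also start fresh
      double dM = M(i - 1, j - 1), dX = X(i - 1, j - 1), dY = Y(i - 1, j - 1);
      double mbest = dM; int mptr = 0;
      if (dX > mbest) { mbest = dX; mptr = 1; }
      if (dY > mbest) { mbest = dY; mptr = 2; }
      if (local && 0.0 > mbest) { mbest = 0.0; mptr = -1; }  // fresh start
      if (mbest > NEG_INF / 2) {
        M(i, j) = mbest + S(i - 1, j - 1);
        pM(i, j) = mptr;
      }
      if (local && M(i, j) < 0) { M(i, j) = NEG_INF; }  // only track >= 0 via fresh start

      // X: gap in B, consume A element i; from (i-1, j)
      double xM = M(i - 1, j) - gop, xX = X(i - 1, j) - gex, xY = Y(i - 1, j) - gop;
      double xbest = xM; int xptr = 0;
      if (xX > xbest) { xbest = xX; xptr = 1; }
      if (xY > xbest) { xbest = xY; xptr = 2; }
      if (xbest > NEG_INF / 2) { X(i, j) = xbest; pX(i, j) = xptr; }

      // Y: gap in A, consume B element j; from (i, j-1)
      // note: X -> Y switch opens a new gap
      double yM = M(i, j - 1) - gop, yX = X(i, j - 1) - gop, yY = Y(i, j - 1) - gex;
      double ybest = yM; int yptr = 0;
      if (yX > ybest) { ybest = yX; yptr = 1; }
      if (yY > ybest) { ybest = yY; yptr = 2; }
      if (ybest > NEG_INF / 2) { Y(i, j) = ybest; pY(i, j) = yptr; }

      if (local && M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  // traceback
  std::vector<int> ai, bj_;
  double score;
  int i, j, state;

  if (local) {
    score = best;
    if (best <= 0.0) {
      return List::create(_["score"] = 0.0,
                          _["a_idx"] = IntegerVector(0),
                          _["b_idx"] = IntegerVector(0));
    }
    i = bi; j = bj; state = 0;
    while (true) {
      if (state == 0) {
        ai.push_back(i); bj_.push_back(j);
        int p = pM(i, j);
        --i; --j;
        if (p == -1) break;           // fresh start: alignment begins here
        state = p;
        if (i == 0 || j == 0) break;  // cannot extend further in local mode
      } else if (state == 1) {
        ai.push_back(i); bj_.push_back(0);
        state = pX(i, j); --i;
      } else {
        ai.push_back(0); bj_.push_back(j);
        state = pY(i, j); --j;
      }
    }
  } else {
    double fM = M(n, m), fX = X(n, m), fY = Y(n, m);
    score = fM; state = 0;
    if (fX > score) { score = fX; state = 1; }
    if (fY > score) { score = fY; state = 2; }
    i = n; j = m;
    while (i > 0 || j > 0) {
      if (state == 0) {
        ai.push_back(i); bj_.push_back(j);
        state = pM(i, j); --i; --j;
      } else if (state == 1) {
        ai.push_back(i); bj_.push_back(0);
        state = pX(i, j); --i;
      } else {
        ai.push_back(0); bj_.push_back(j);
        state = pY(i, j); --j;
      }
    }
  }

  std::reverse(ai.begin(), ai.end());
  std::reverse(bj_.begin(), bj_.end());
  return List::create(_["score"] = score,
                      _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bj_));
}
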