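#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Profile-HMM Viterbi / forward over a local-in-sequence, global-in-model
// architecture: free flanking states (log-odds 0 per background residue)
// allow the model to start and end anywhere in the sequence; the model
// itself is traversed begin-to-end through match/insert/delete states.
//
// All scores are log2-odds against the background. Layout (k = 0..L):
//   tM(k, .) : from M_k (M_0 = begin) to { M_{k+1} (or end at k = L), I_k, D_{k+1} }
//   tI(k, .) : from I_k to { M_{k+1} (end at k = L), I_k, D_{k+1} }
//   tD(k, .) : from D_k to { M_{k+1} (end at k = L), I_k, D_{k+1} }, row 0 unused
//   match_lo : L x 20, insert_lo : (L+1) x 20 (rows I_0..I_L)

static const double NEG_INF = -1e300;

static inline double lse2(double a, double b) {
  if (a < b) std::swap(a, b);
  if (b <= NEG_INF / 2) return a;
  return a + std::log1p(std::exp((b - a) * M_LN2)) / M_LN2;
}

// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
List hmm_viterbi_cpp(IntegerVector seq, NumericMatrix match_lo,
                     NumericMatrix ins_lo, NumericMatrix tM,
                     NumericMatrix tI, NumericMatrix tD) {
  const int L = match_lo.nrow();
  const int n = seq.size();

  NumericMatrix VM(L + 1, n + 1), VI(L + 1, n + 1), VD(L + 1, n + 1);
  IntegerMatrix pM(L + 1, n + 1), pI(L + 1, n + 1), pD(L + 1, n + 1);
  std::fill(VM.begin(), VM.end(), NEG_INF);
  std::fill(VI.begin(), VI.end(), NEG_INF);
  std::fill(VD.begin(), VD.end(), NEG_INF);

  for (int i = 0; i <= n; ++i) VM(0, i) = 0.0;  // begin reachable after any flank
  // all-delete entry at column 0
  VD(1, 0) = tM(0, 2); pD(1, 0) = 0;
  for (int k = 2; k <= L; ++k) { VD(k, 0) = VD(k - 1, 0) + tD(k - 1, 2); pD(k, 0) = 2; }

  for (int i = 1; i <= n; ++i) {
    const int x = seq[i - 1] - 1;
    for (int k = 1; k <= L; ++k) {
      double cM = VM(k - 1, i - 1) + tM(k - 1, 0);
      double cI = VI(k - 1, i - 1) + tI(k - 1, 0);
      double cD = VD(k - 1, i - 1) + tD(k - 1, 0);
      double best = cM; int ptr = 0;
      if (cI > best) { best = cI; ptr = 1; }
      if (cD > best) { best = cD; ptr = 2; }
      if (best > NEG_INF / 2) { VM(k, i) = best + match_lo(k - 1, x); pM(k, i) = ptr; }
    }
    for (int k = 0; k <= L; ++k) {
      double cM = VM(k, i - 1) + tM(k, 1);
      double cI = VI(k, i - 1) + tI(k, 1);
      double cD = (k >= 1) ? VD(k, i - 1) + tD(k, 1) : NEG_INF;
      double best = cM; int ptr = 0;
      if (cI > best) { best = cI; ptr = 1; }
      if (cD > best) { best = cD; ptr = 2; }
      if (best > NEG_INF / 2) { VI(k, i) = best + ins_lo(k, x); pI(k, i) = ptr; }
    }
    for (int k = 1; k <= L; ++k) {
      double cM = VM(k - 1, i) + tM(k - 1, 2);
      double cI = VI(k - 1, i) + tI(k - 1, 2);
      double cD = (k >= 2) ? VD(k - 1, i) + tD(k - 1, 2) : NEG_INF;
      double best = cM; int ptr = 0;
      if (cI > best) { best = cI; ptr = 1; }
      if (cD > best) { best = cD; ptr = 2; }
      if (best > NEG_INF / 2) { VD(k, i) = best; pD(k, i) = ptr; }
    }
  }

  // exit: from M_L, I_L or D_L at any i
  double score = NEG_INF; int ei = 0, etype = 0;
  for (int i = 0; i <= n; ++i) {
    double cM = VM(L, i) + tM(L, 0);
    double cI = VI(L, i) + tI(L, 0);
    double cD = VD(L, i) + tD(L, 0);
    if (cM > score) { score = cM; ei = i; etype = 0; }
    if (cI > score) { score = cI; ei = i; etype = 1; }
    if (cD > score) { score = cD; ei = i; etype = 2; }
  }

  // traceback
  std::vector<int> st_type, st_k, st_pos;
  int k = L, i = ei, type = etype;
  while (!(type == 0 && k == 0)) {
    st_type.push_back(type); st_k.push_back(k);
    int ptr;
    if (type == 0) {
      st_pos.push_back(i); ptr = pM(k, i); --k; --i;
    } else if (type == 1) {
      st_pos.push_back(i); ptr = pI(k, i); --i;        // insert stays at k
    } else {
      st_pos.push_back(0); ptr = pD(k, i); --k;
    }
    type = ptr;
    if (type == 0 && k == 0) break;
  }
  std::reverse(st_type.begin(), st_type.end());
  std::reverse(st_k.begin(), st_k.end());
  std::reverse(st_pos.begin(), st_pos.end());

  int start = 0, end = 0;
  for (size_t s = 0; s < st_pos.size(); ++s) {
    if (st_pos[s] > 0) { if (start == 0) start = st_pos[s]; end = st_pos[s]; }
  }

  return List::create(_["score"] = score, _["state_type"] = wrap(st_type),
                      _["state_k"] = wrap(st_k), _["seq_pos"] = wrap(st_pos),
                      _["start"] = start, _["end"] = end);
}

// [[Rcpp::export(name = ".hmm_forward_cpp")]]
double hmm_forward_cpp(IntegerVector seq, NumericMatrix match_lo,
                       NumericMatrix ins_lo, NumericMatrix tM,
                       NumericMatrix tI, NumericMatrix tD) {
  const int L = match_lo.nrow();
  const int n = seq.size();

  NumericMatrix FM(L + 1, n + 1), FI(L + 1, n + 1), FD(L + 1, n + 1);
  std::fill(FM.begin(), FM.end(), NEG_INF);
  std::fill(FI.begin(), FI.end(), NEG_INF);
  std::fill(FD.begin(), FD.end(), NEG_INF);

  for (int i = 0; i <= n; ++i) FM(0, i) = 0.0;
  FD(1, 0) = tM(0, 2);
  for (int k = 2; k <= L; ++k) FD(k, 0) = FD(k - 1, 0) + tD(k - 1, 2);

  for (int i = 1; i <= n; ++i) {
    const int x = seq[i - 1] - 1;
    for (int k = 1; k <= L; ++k) {
      double acc = lse2(FM(k - 1, i - 1) + tM(k - 1, 0),
                        lse2(FI(k - 1, i - 1) + tI(k - 1, 0),
                             FD(k - 1, i - 1) + tD(k - 1, 0)));
      if (acc > NEG_INF / 2) FM(k, i) = acc + match_lo(k - 1, x);
    }
    for (int k = 0; k <= L; ++k) {
      double acc = lse2(FM(k, i - 1) + tM(k, 1), FI(k, i - 1) + tI(k, 1));
      if (k >= 1) acc = lse2(acc, FD(k, i - 1) + tD(k, 1));
      if (acc > NEG_INF / 2) FI(k, i) = acc + ins_lo(k, x);
    }
    for (int k = 1; k <= L; ++k) {
      double acc = lse2(FM(k - 1, i) + tM(k - 1, 2), FI(k - 1, i) + tI(k - 1, 2));
      if (k >= 2) acc = lse2(acc, FD(k - 1, i) + tD(k - 1, 2));
      FD(k, i) = acc;
    }
  }

  double score = NEG_INF;
  for (int i = 0; i <= n; ++i) {
    double e = lse2(FM(L, i) + tM(L, 0),
                    lse2(FI(L, i) + tI(L, 0), FD(L, i) + tD(L, 0)));
    score = lse2(score, e);
  }
  return score;
}
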