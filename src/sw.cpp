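#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh three-state
// recursion). A gap of length L costs gapOpen + L * gapExtend; transitions
// between the two gap states are allowed, so adjacent insertions and
// deletions each pay a full gap opening. q and t are 1-based indices into
// the rows/columns of S. Returns the best score, the 1-based start
// coordinates, and the aligned index vectors (0 marks a gap).
//
// [[Rcpp::export]]
List sw_align(IntegerVector q, IntegerVector t, NumericMatrix S,
              double gapOpen, double gapExtend) {
  const int n = q.size(), m = t.size();
  const double openCost = gapOpen + gapExtend;  // first gapped residue
  // H: match/mismatch state, E: gap in query (consumes t), F: gap in t
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix PH(n + 1, m + 1), PE(n + 1, m + 1), PF(n + 1, m + 1);
  const double NEG = -1e18;
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }
  for (int j = 0; j <= m; ++j) { E(0, j) = NEG; F(0, j) = NEG; }

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // E: gap in query ending at (i, j): came from (i, j-1)
      double eH = H(i, j - 1) - openCost;
      double eE = E(i, j - 1) - gapExtend;
      double eF = F(i, j - 1) - openCost;
      if (eH >= eE && eH >= eF)      { E(i, j) = eH; PE(i, j) = 0; }
      else if (eE >= eF)             { E(i, j) = eE; PE(i, j) = 1; }
      else                           { E(i, j) = eF; PE(i, j) = 2; }
      // F: gap in target ending at (i, j): came from (i-1, j)
      double fH = H(i - 1, j) - openCost;
      double fE = E(i - 1, j) - openCost;
      double fF = F(i - 1, j) - gapExtend;
      if (fH >= fE && fH >= fF)      { F(i, j) = fH; PF(i, j) = 0; }
      else if (fE >= fF)             { F(i, j) = fE; PF(i, j) = 1; }
      else                           { F(i, j) = fF; PF(i, j) = 2; }
      // H: aligned pair at (i, j), or best gap state, clipped at 0 (local)
      double sub = S(q[i - 1] - 1, t[j - 1] - 1);
      double hM = H(i - 1, j - 1) + sub;
      double h = hM; int ph = 0;            // 0 = diagonal from H
      if (E(i, j) > h) { h = E(i, j); ph = 1; }
      if (F(i, j) > h) { h = F(i, j); ph = 2; }
      if (h < 0) { h = 0; ph = 3; }         // 3 = local restart
      H(i, j) = h; PH(i, j) = ph;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::vector<int> qa, ta;
  int i = bi, j = bj, state = 0;  // trace from H at the best cell
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (PH(i, j) == 3 || H(i, j) == 0) break;
      if (PH(i, j) == 0) {
        qa.push_back(i); ta.push_back(j); --i; --j;
      } else state = PH(i, j);
    } else if (state == 1) {       // E: gap in query
      int p = PE(i, j);
      qa.push_back(0); ta.push_back(j); --j;
      state = p;
    } else {                       // F: gap in target
      int p = PF(i, j);
      qa.push_back(i); ta.push_back(0); --i;
      state = p;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());

  int qs = 0, ts = 0;
  for (size_t k = 0; k < qa.size(); ++k) if (qa[k] > 0) { qs = qa[k]; break; }
  for (size_t k = 0; k < ta.size(); ++k) if (ta[k] > 0) { ts = ta[k]; break; }

  return List::create(_["score"] = best,
                      _["q_start"] = qs, _["t_start"] = ts,
                      _["q_idx"] = IntegerVector(qa.begin(), qa.end()),
                      _["t_idx"] = IntegerVector(ta.begin(), ta.end()));
}
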