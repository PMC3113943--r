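#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// X-drop seed extension in the original amino-acid alphabet.
// Sequences are 1-based integer codes indexing the substitution matrix.

static inline double subst(const NumericMatrix& mat, int a, int b) {
  return mat(a - 1, b - 1);
}

// Ungapped extension: keep the seed fixed, extend left and right on the
// diagonal, each direction stopping once the running score drops more
// than xdrop below the running maximum. Returns
// (qstart, qend, sstart, send, score, anchor_q) with the anchor at the
// highest-scoring single column of the final segment.
// [[Rcpp::export]]
NumericVector ungapped_extend_cpp(IntegerVector q, IntegerVector s,
                                  int qbeg, int sbeg, int len,
                                  NumericMatrix mat, double xdrop) {
  const int m = q.size(), n = s.size();
  double seed_score = 0.0;
  for (int k = 0; k < len; ++k)
    seed_score += subst(mat, q[qbeg - 1 + k], s[sbeg - 1 + k]);
  // right
  double run = 0.0, best_r = 0.0;
  int qe = qbeg + len - 1, se = sbeg + len - 1, best_qe = qe;
  for (int i = qe + 1, j = se + 1; i <= m && j <= n; ++i, ++j) {
    run += subst(mat, q[i - 1], s[j - 1]);
    if (run > best_r) { best_r = run; best_qe = i; }
    else if (run < best_r - xdrop) break;
  }
  // left
  run = 0.0;
  double best_l = 0.0;
  int best_qs = qbeg;
  for (int i = qbeg - 1, j = sbeg - 1; i >= 1 && j >= 1; --i, --j) {
    run += subst(mat, q[i - 1], s[j - 1]);
    if (run > best_l) { best_l = run; best_qs = i; }
    else if (run < best_l - xdrop) break;
  }
  double total = seed_score + best_r + best_l;
  // anchor: highest-scoring column of the segment
  int qs = best_qs, ss = sbeg - (qbeg - best_qs);
  int seg_len = best_qe - best_qs + 1;
  double best_col = R_NegInf; int anchor_q = qbeg;
  for (int k = 0; k < seg_len; ++k) {
    double c = subst(mat, q[qs - 1 + k], s[ss - 1 + k]);
    if (c > best_col) { best_col = c; anchor_q = qs + k; }
  }
  return NumericVector::create(qs, best_qe, ss, ss + seg_len - 1, total,
                               anchor_q);
}

// one-directional affine-gap X-drop DP from an implicit corner (0,0);
// A and B are the residues beyond the anchor, in extension order.
// ops collects the traceback (0 = aligned pair, 1 = gap in B consuming A,
// 2 = gap in A consuming B), from the corner outward.
static double half_extend(const std::vector<int>& A, const std::vector<int>& B,
                          const NumericMatrix& mat, double gap_open,
                          double gap_ext, double xdrop,
                          std::vector<int>& ops) {
  const int la = (int)A.size(), lb = (int)B.size();
  const double NEG = -1e30;
  const int W = lb + 1;
  std::vector<double> M((la + 1) * W, NEG), X(M), Y(M);
  std::vector<signed char> tM((la + 1) * W, -1), tX(tM), tY(tM);
  auto idx = [W](int i, int j) { return i * W + j; };
  M[idx(0, 0)] = 0.0;
  double best = 0.0;
  int bi = 0, bj = 0, bstate = 0;
  for (int j = 1; j <= lb; ++j) {
    double v = -(gap_open + j * gap_ext);
    if (v >= best - xdrop) { Y[idx(0, j)] = v; tY[idx(0, j)] = 2; }
  }
  for (int i = 1; i <= la; ++i) {
    double vx = -(gap_open + i * gap_ext);
    if (vx >= best - xdrop) { X[idx(i, 0)] = vx; tX[idx(i, 0)] = 1; }
    for (int j = 1; j <= lb; ++j) {
      const int c = idx(i, j), d = idx(i - 1, j - 1);
      const int u = idx(i - 1, j), l = idx(i, j - 1);
      // aligned pair
      double pm = std::max(M[d], std::max(X[d], Y[d]));
      if (pm > NEG / 2) {
        double v = pm + subst(mat, A[i - 1], B[j - 1]);
        if (v >= best - xdrop) {
          M[c] = v;
          tM[c] = (M[d] >= X[d] && M[d] >= Y[d]) ? 0 : (X[d] >= Y[d] ? 1 : 2);
        }
      }
      // gap consuming A (vertical)
      double xo = (M[u] > NEG / 2) ? M[u] - gap_open - gap_ext : NEG;
      double xe = (X[u] > NEG / 2) ? X[u] - gap_ext : NEG;
      double vx2 = std::max(xo, xe);
      if (vx2 >= best - xdrop && vx2 > NEG / 2) {
        X[c] = vx2; tX[c] = (xo >= xe) ? 0 : 1;
      }
      // gap consuming B (horizontal)
      double yo = (M[l] > NEG / 2) ? M[l] - gap_open - gap_ext : NEG;
      double ye = (Y[l] > NEG / 2) ? Y[l] - gap_ext : NEG;
      double vy = std::max(yo, ye);
      if (vy >= best - xdrop && vy > NEG / 2) {
        Y[c] = vy; tY[c] = (yo >= ye) ? 0 : 2;
      }
      if (M[c] > best) { best = M[c]; bi = i; bj = j; bstate = 0; }
    }
  }
  // traceback from the best aligned-pair cell to the corner
  ops.clear();
  int i = bi, j = bj, st = bstate;
  while (i > 0 || j > 0) {
    if (st == 0) {
      int prev = tM[idx(i, j)];
      ops.push_back(0); --i; --j; st = prev;
    } else if (st == 1) {
      int prev = tX[idx(i, j)];
      ops.push_back(1); --i; st = prev;
    } else {
      int prev = tY[idx(i, j)];
      ops.push_back(2); --j; st = prev;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return best;
}

// Gapped extension outward from an anchor column (aq, as), both 1-based;
// the anchor pair is always part of the alignment. Returns the stitched
// alignment (0 in qaln/saln marks a gap) and its score.
// [[Rcpp::export]]
List gapped_extend_cpp(IntegerVector q, IntegerVector s, int aq, int as,
                       NumericMatrix mat, double gap_open, double gap_ext,
                       double xdrop) {
  const int m = q.size(), n = s.size();
  std::vector<int> Ar, Br, Al, Bl;
  for (int i = aq + 1; i <= m; ++i) Ar.push_back(q[i - 1]);
  for (int j = as + 1; j <= n; ++j) Br.push_back(s[j - 1]);
  for (int i = aq - 1; i >= 1; --i) Al.push_back(q[i - 1]);
  for (int j = as - 1; j >= 1; --j) Bl.push_back(s[j - 1]);
  std::vector<int> ops_r, ops_l;
  double sr = half_extend(Ar, Br, mat, gap_open, gap_ext, xdrop, ops_r);
  double sl = half_extend(Al, Bl, mat, gap_open, gap_ext, xdrop, ops_l);
  double score = sl + subst(mat, q[aq - 1], s[as - 1]) + sr;
  // assemble aligned sequences: left ops reversed, anchor, right ops
  std::vector<int> qa, sa;
  int qi = aq, sj = as;  // walk left
  std::vector<int> qa_l, sa_l;
  for (int op : ops_l) {
    if (op == 0) { --qi; --sj; qa_l.push_back(q[qi - 1]); sa_l.push_back(s[sj - 1]); }
    else if (op == 1) { --qi; qa_l.push_back(q[qi - 1]); sa_l.push_back(0); }
    else { --sj; qa_l.push_back(0); sa_l.push_back(s[sj - 1]); }
  }
  int qstart = qi, sstart = sj;
  std::reverse(qa_l.begin(), qa_l.end());
  std::reverse(sa_l.begin(), sa_l.end());
  qa = qa_l; sa = sa_l;
  qa.push_back(q[aq - 1]); sa.push_back(s[as - 1]);
  qi = aq; sj = as;
  for (int op : ops_r) {
    if (op == 0) { ++qi; ++sj; qa.push_back(q[qi - 1]); sa.push_back(s[sj - 1]); }
    else if (op == 1) { ++qi; qa.push_back(q[qi - 1]); sa.push_back(0); }
    else { ++sj; qa.push_back(0); sa.push_back(s[sj - 1]); }
  }
  return List::create(_["score"] = score, _["qstart"] = qstart,
                      _["qend"] = qi, _["sstart"] = sstart, _["send"] = sj,
                      _["qaln"] = wrap(qa), _["saln"] = wrap(sa));
}
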