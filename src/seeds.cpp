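#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Seed search over the suffix array of the reduced database text.
// Encoding contract (see R/db_index.R): group symbols are positive
// integers; sentinels and database wildcard positions are distinct
// negative codes (they can never equal anything); query wildcards are 0.

// compare suffix text[pos..] against pattern pat[from..from+len) symbolwise;
// returns <0, 0, >0 like strcmp, treating the pattern as truncated at len.
static int cmp_suffix_pattern(const std::vector<double>& txt, int pos,
                              const std::vector<double>& pat, int from,
                              int len) {
  const int n = (int)txt.size();
  for (int k = 0; k < len; ++k) {
    if (pos + k >= n) return -1;  // suffix exhausted => suffix < pattern
    double a = txt[pos + k], b = pat[from + k];
    if (a < b) return -1;
    if (a > b) return 1;
  }
  return 0;  // pattern is a prefix of the suffix
}

// [lo, hi) range of suffixes having pat[from..from+len) as a prefix
static void sa_range(const std::vector<double>& txt,
                     const IntegerVector& sa,
                     const std::vector<double>& pat, int from, int len,
                     int& lo, int& hi) {
  int n = sa.size();
  // lower bound: first suffix >= pattern
  int a = 0, b = n;
  while (a < b) {
    int mid = (a + b) / 2;
    if (cmp_suffix_pattern(txt, sa[mid] - 1, pat, from, len) < 0) a = mid + 1;
    else b = mid;
  }
  lo = a;
  // upper bound: first suffix whose prefix compares > pattern
  b = n;
  while (a < b) {
    int mid = (a + b) / 2;
    if (cmp_suffix_pattern(txt, sa[mid] - 1, pat, from, len) <= 0) a = mid + 1;
    else b = mid;
  }
  hi = a;
}

static int forward_match_len(const std::vector<double>& txt, int tpos,
                             const std::vector<double>& qry, int qpos) {
  int l = 0;
  const int n = (int)txt.size(), m = (int)qry.size();
  while (qpos + l < m && tpos + l < n && txt[tpos + l] == qry[qpos + l]) ++l;
  return l;
}

struct Seed { int qpos, tpos, len, mm; };

// MEM seeds: for every query position p, all database suffixes sharing a
// common prefix of at least minlen[p] symbols, each reported at the full
// forward match length; matches wholly contained in a longer reported
// match on the same diagonal are suppressed.
// [[Rcpp::export]]
DataFrame sa_mems_cpp(NumericVector text, IntegerVector sa,
                      NumericVector query, IntegerVector minlens) {
  std::vector<double> txt(text.begin(), text.end());
  std::vector<double> qry(query.begin(), query.end());
  const int m = (int)qry.size();
  std::vector<Seed> out;
  for (int p = 0; p + 6 <= m; ++p) {
    int L = minlens[p];
    if (L == NA_INTEGER || L < 6 || p + L > m) continue;
    bool has_wild = false;
    for (int k = 0; k < L; ++k) if (qry[p + k] <= 0) { has_wild = true; break; }
    if (has_wild) continue;  // wildcards never seed
    int lo, hi;
    sa_range(txt, sa, qry, p, L, lo, hi);
    for (int i = lo; i < hi; ++i) {
      int t = sa[i] - 1;
      int len = forward_match_len(txt, t, qry, p);
      out.push_back(Seed{p, t, len, -1});
    }
  }
  // containment suppression per diagonal (matches never cross sentinels,
  // so a diagonal uniquely identifies a database record)
  std::sort(out.begin(), out.end(), [](const Seed& a, const Seed& b) {
    long long da = (long long)a.tpos - a.qpos, db = (long long)b.tpos - b.qpos;
    if (da != db) return da < db;
    if (a.qpos != b.qpos) return a.qpos < b.qpos;
    return a.len > b.len;
  });
  std::vector<Seed> kept;
  long long cur_diag = 0; int max_end = -1; bool first = true;
  for (const Seed& s : out) {
    long long d = (long long)s.tpos - s.qpos;
    if (first || d != cur_diag) { cur_diag = d; max_end = -1; first = false; }
    int e = s.qpos + s.len;
    if (e <= max_end) continue;  // contained in a previously kept match
    kept.push_back(s);
    max_end = e;
  }
  int n = (int)kept.size();
  IntegerVector qp(n), tp(n), ln(n);
  for (int i = 0; i < n; ++i) {
    qp[i] = kept[i].qpos + 1; tp[i] = kept[i].tpos + 1; ln[i] = kept[i].len;
  }
  return DataFrame::create(_["qpos"] = qp, _["tpos"] = tp, _["len"] = ln);
}

// Single-mismatch seeds: length-10 query windows matched exactly except
// for one substituted position (4th-7th seed column), found by replacing
// that symbol by every other reduced symbol in turn and searching the
// suffix array for exact occurrences; matches are extended forward
// maximally past the window.
// [[Rcpp::export]]
DataFrame sa_mismatch_seeds_cpp(NumericVector text, IntegerVector sa,
                                NumericVector query, int n_symbols) {
  std::vector<double> txt(text.begin(), text.end());
  std::vector<double> qry(query.begin(), query.end());
  const int m = (int)qry.size();
  const int W = 10;
  std::vector<Seed> out;
  std::vector<double> pat(W);
  for (int p = 0; p + W <= m; ++p) {
    bool has_wild = false;
    for (int k = 0; k < W; ++k) {
      pat[k] = qry[p + k];
      if (pat[k] <= 0) has_wild = true;
    }
    if (has_wild) continue;
    for (int off = 3; off <= 6; ++off) {  // 0-based mismatch offsets 3..6
      double orig = pat[off];
      for (int s = 1; s <= n_symbols; ++s) {
        if ((double)s == orig) continue;
        pat[off] = (double)s;
        int lo, hi;
        sa_range(txt, sa, pat, 0, W, lo, hi);
        for (int i = lo; i < hi; ++i) {
          int t = sa[i] - 1;
          int len = W;
          const int n = (int)txt.size();
          while (p + len < m && t + len < n && txt[t + len] == qry[p + len])
            ++len;
          out.push_back(Seed{p, t, len, off});
        }
      }
      pat[off] = orig;
    }
  }
  int n = (int)out.size();
  IntegerVector qp(n), tp(n), ln(n), mm(n);
  for (int i = 0; i < n; ++i) {
    qp[i] = out[i].qpos + 1; tp[i] = out[i].tpos + 1; ln[i] = out[i].len;
    mm[i] = out[i].mm + 1;  // 1-based position within the seed (4..7)
  }
  return DataFrame::create(_["qpos"] = qp, _["tpos"] = tp, _["len"] = ln,
                           _["mismatch_pos"] = mm);
}
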