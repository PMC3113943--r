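#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Suffix array by prefix doubling (O(n log^2 n)); text is an arbitrary
// integer vector (sentinels are distinct negative codes, so every suffix
// comparison terminates before running off a sequence boundary).
static std::vector<int> suffix_array_int(const std::vector<long long>& txt) {
  const int n = (int)txt.size();
  std::vector<int> sa(n), rnk(n), tmp(n);
  // initial ranks: compress text values
  {
    std::vector<std::pair<long long, int> > v(n);
    for (int i = 0; i < n; ++i) v[i] = std::make_pair(txt[i], i);
    std::sort(v.begin(), v.end());
    int r = 0;
    for (int i = 0; i < n; ++i) {
      if (i > 0 && v[i].first != v[i - 1].first) ++r;
      rnk[v[i].second] = r;
    }
    for (int i = 0; i < n; ++i) sa[i] = i;
  }
  for (int k = 1;; k <<= 1) {
    // sort suffixes by (rank[i], rank[i+k])
    auto key2 = [&](int i) { return (i + k < n) ? rnk[i + k] : -1; };
    auto cmp = [&](int a, int b) {
      if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
      return key2(a) < key2(b);
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rnk = tmp;
    if (rnk[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// Kasai's algorithm: lcp[i] = LCP(suffix sa[i-1], suffix sa[i]), lcp[0] = 0.
static std::vector<int> lcp_kasai(const std::vector<long long>& txt,
                                  const std::vector<int>& sa) {
  const int n = (int)txt.size();
  std::vector<int> rnk(n), lcp(n, 0);
  for (int i = 0; i < n; ++i) rnk[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rnk[i] > 0) {
      int j = sa[rnk[i] - 1];
      while (i + h < n && j + h < n && txt[i + h] == txt[j + h]) ++h;
      lcp[rnk[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return lcp;
}

static std::vector<long long> as_ll(const NumericVector& txt) {
  std::vector<long long> t(txt.size());
  for (int i = 0; i < (int)txt.size(); ++i) t[i] = (long long)txt[i];
  return t;
}

// Build suffix array + LCP over the encoded text, then drop sentinel
// positions (keep[i] == FALSE); LCP entries across removed suffixes are
// the running minimum over the removed span. Returns 1-based positions.
// [[Rcpp::export]]
List build_suffix_index_cpp(NumericVector text, LogicalVector keep) {
  std::vector<long long> txt = as_ll(text);
  const int n = (int)txt.size();
  if (n == 0) return List::create(_["sa"] = IntegerVector(0),
                                  _["lcp"] = IntegerVector(0));
  std::vector<int> sa = suffix_array_int(txt);
  std::vector<int> lcp = lcp_kasai(txt, sa);
  std::vector<int> fsa, flcp;
  fsa.reserve(n); flcp.reserve(n);
  int pend_min = -1;  // -1: nothing pending (first kept suffix)
  for (int i = 0; i < n; ++i) {
    int l = (i == 0) ? 0 : lcp[i];
    if (pend_min < 0) pend_min = l; else pend_min = std::min(pend_min, l);
    if (keep[sa[i]]) {
      flcp.push_back(fsa.empty() ? 0 : pend_min);
      fsa.push_back(sa[i] + 1);
      pend_min = -1;
    }
  }
  return List::create(_["sa"] = wrap(fsa), _["lcp"] = wrap(flcp));
}
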