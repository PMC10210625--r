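#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static std::string revcomp_sa(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default:  c = 'N';
    }
  }
  return r;
}

// suffix array by prefix doubling with radix sort (O(n log n))
static void build_sa(const std::string &t, std::vector<int> &sa,
                     std::vector<int> &rank_) {
  const int n = (int)t.size();
  sa.resize(n); rank_.resize(n);
  std::vector<int> tmp(n), cnt(std::max(n, 256), 0);

  for (int i = 0; i < n; ++i) rank_[i] = (unsigned char)t[i];
  // initial counting sort by first character
  std::fill(cnt.begin(), cnt.begin() + 256, 0);
  for (int i = 0; i < n; ++i) ++cnt[rank_[i]];
  for (int i = 1; i < 256; ++i) cnt[i] += cnt[i - 1];
  for (int i = n - 1; i >= 0; --i) sa[--cnt[rank_[i]]] = i;

  for (int k = 1; k < n; k <<= 1) {
    // sort by second key (rank_[i+k]) : suffixes i >= n-k have empty second key
    int p = 0;
    for (int i = n - k; i < n; ++i) tmp[p++] = i;
    for (int i = 0; i < n; ++i)
      if (sa[i] >= k) tmp[p++] = sa[i] - k;
    // stable counting sort by first key rank_[i]
    std::fill(cnt.begin(), cnt.begin() + n, 0);
    for (int i = 0; i < n; ++i) ++cnt[rank_[i]];
    for (int i = 1; i < n; ++i) cnt[i] += cnt[i - 1];
    for (int i = n - 1; i >= 0; --i) sa[--cnt[rank_[tmp[i]]]] = tmp[i];
    // re-rank
    std::vector<int> nr(n);
    nr[sa[0]] = 0;
    int r = 0;
    for (int i = 1; i < n; ++i) {
      int a = sa[i - 1], b = sa[i];
      bool same = rank_[a] == rank_[b] &&
        ((a + k < n ? rank_[a + k] : -1) == (b + k < n ? rank_[b + k] : -1));
      nr[b] = same ? r : ++r;
    }
    rank_.swap(nr);
    if (r == n - 1) break;
  }
}

// Kasai LCP: lcp[i] = lcp(suffix sa[i-1], suffix sa[i]) for i in 1..n-1
static void build_lcp(const std::string &t, const std::vector<int> &sa,
                      const std::vector<int> &rank_, std::vector<int> &lcp) {
  const int n = (int)t.size();
  lcp.assign(n, 0);
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank_[i] > 0) {
      int j = sa[rank_[i] - 1];
      while (i + h < n && j + h < n && t[i + h] == t[j + h]) ++h;
      lcp[rank_[i]] = h;
      if (h > 0) --h;
    } else h = 0;
  }
}

// Maximal exact matches of a sequence against itself (both orientations).
// The text indexed is seq + sentinel + revcomp(seq); a MEM is a pair of
// suffixes with lcp >= min_len whose preceding characters differ
// (left-maximal; right-maximality is the lcp itself). Pairs with both
// members in the reverse-complement half mirror forward-half pairs and are
// skipped; inverted matches are deduplicated downstream in R.
// [[Rcpp::export]]
List sa_mems_cpp(std::string seq, int min_len, double max_segments) {
  const int n = (int)seq.size();
  std::string t = seq;
  t.push_back('\x01');
  t += revcomp_sa(seq);
  const int m = (int)t.size();

  std::vector<int> sa, rank_, lcp;
  build_sa(t, sa, rank_);
  build_lcp(t, sa, rank_, lcp);

  std::vector<int> A1, A2, B1, B2, LEN;
  std::vector<int> STR;   // 0 = '+', 1 = '-'

  double pair_budget = 0;

  // blocks of consecutive suffixes with adjacent lcp >= min_len
  int i = 1;
  while (i < m) {
    if (lcp[i] < min_len) { ++i; continue; }
    int lo = i - 1;         // block spans sa[lo..hi]
    int hi = i;
    while (hi + 1 < m && lcp[hi + 1] >= min_len) ++hi;
    const int bs = hi - lo + 1;
    pair_budget += (double)bs * (bs - 1) / 2.0;
    if (pair_budget > max_segments)
      stop("self-alignment match count exceeds max_segments (%.0f); raise min_len or max_segments", max_segments);
    for (int p = lo; p <= hi; ++p) {
      int rmin = INT_MAX;
      for (int q = p + 1; q <= hi; ++q) {
        rmin = std::min(rmin, lcp[q]);
        if (rmin < min_len) break;
        int a = sa[p], b = sa[q];
        // left-maximality
        char ca = (a == 0) ? '\0' : t[a - 1];
        char cb = (b == 0) ? '\0' : t[b - 1];
        if (a != 0 && b != 0 && ca == cb) continue;
        bool a_fwd = a < n, b_fwd = b < n;
        if (!a_fwd && !b_fwd) continue;   // mirror of a forward pair
        const int L = rmin;
        int as, ae, bs2, be, strand;
        if (a_fwd && b_fwd) {
          strand = 0;
          as = a; ae = a + L; bs2 = b; be = b + L;
        } else {
          strand = 1;
          int f = a_fwd ? a : b;          // forward-half position
          int r = a_fwd ? b : a;          // revcomp-half position
          int q2 = r - n - 1;             // coordinate within revcomp(seq)
          as = f; ae = f + L;
          bs2 = n - q2 - L; be = n - q2;
        }
        // canonical interval order
        if (bs2 < as || (bs2 == as && be < ae)) {
          std::swap(as, bs2); std::swap(ae, be);
        }
        A1.push_back(as); A2.push_back(ae);
        B1.push_back(bs2); B2.push_back(be);
        LEN.push_back(L); STR.push_back(strand);
      }
    }
    i = hi + 1;
  }

  return List::create(_["a_start"] = wrap(A1), _["a_end"] = wrap(A2),
                      _["b_start"] = wrap(B1), _["b_end"] = wrap(B2),
                      _["length"] = wrap(LEN), _["strand"] = wrap(STR));
}
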