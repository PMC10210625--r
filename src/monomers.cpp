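#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <deque>
using namespace Rcpp;

static inline int bc(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static std::string revcomp_str(const std::string &s) {
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

struct Cand {
  int start;
  int fam;      // 0-based family index
  int strand;   // 0 = '+', 1 = '-'
  double div;
  int len;
};

// Greedy non-overlapping tiling of monomer consensi onto a sequence.
// Candidate anchors come from exact shared k-mers with the doubled
// consensus (both strands); candidates are scored by Hamming divergence,
// accepted best-first, then extended outward in tandem steps so mutated
// copies inside arrays are rescued even when no seed survives.
// [[Rcpp::export]]
List map_monomers_cpp(std::string seq, CharacterVector consensi,
                      double max_divergence) {
  const int n = seq.size();
  const int nf = consensi.size();

  std::vector<std::string> cons(2 * nf);  // [f*2 + strand]
  for (int f = 0; f < nf; ++f) {
    cons[2 * f] = as<std::string>(consensi[f]);
    cons[2 * f + 1] = revcomp_str(cons[2 * f]);
  }

  std::vector<Cand> cands;
  std::unordered_set<long long> seen;
  auto key_of = [&](int start, int f, int strand) {
    return ((long long)start * nf + f) * 2 + strand;
  };

  auto hamming_div = [&](int start, const std::string &m) {
    const int L = (int)m.size();
    int mm = 0;
    for (int i = 0; i < L; ++i)
      if (seq[start + i] != m[i]) ++mm;
    return (double)mm / (double)L;
  };

  // seed candidates from shared k-mers
  for (int f = 0; f < nf; ++f) {
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &m = cons[2 * f + strand];
      const int L = (int)m.size();
      const int k = std::min(8, L);
      const long long mask = (1LL << (2 * k)) - 1;
      // k-mer -> offsets within doubled consensus (mod L for anchors)
      std::unordered_map<long long, std::vector<int>> offs;
      {
        std::string dd = m + m;
        long long kc = 0;
        int bad = -1;
        for (int i = 0; i < (int)dd.size(); ++i) {
          int c = bc(dd[i]);
          if (c < 0) { bad = i; continue; }
          kc = ((kc << 2) | c) & mask;
          if (i - bad >= k && i + 1 >= k) {
            int pos = i - k + 1;
            if (pos < 2 * L - k + 1) offs[kc].push_back(pos);
          }
        }
      }
      long long kc = 0;
      int bad = -1;
      for (int i = 0; i < n; ++i) {
        int c = bc(seq[i]);
        if (c < 0) { bad = i; continue; }
        kc = ((kc << 2) | c) & mask;
        if (i - bad >= k && i + 1 >= k) {
          auto it = offs.find(kc);
          if (it == offs.end()) continue;
          const int p = i - k + 1;
          for (int off : it->second) {
            int anchor = p - off;
            for (int a : {anchor, anchor + L}) {
              if (a < 0 || a + L > n) continue;
              long long kk = key_of(a, f, strand);
              if (seen.count(kk)) continue;
              seen.insert(kk);
              double d = hamming_div(a, m);
              if (d <= max_divergence)
                cands.push_back({a, f, strand, d, L});
            }
          }
        }
      }
    }
  }

  // longest placements first: an acceptable long-family placement is
  // near-certainly a true copy, while a short-family placement can be a
  // chance match (a mutated long monomer can contain the short motif)
  std::stable_sort(cands.begin(), cands.end(), [](const Cand &x, const Cand &y) {
    if (x.len != y.len) return x.len > y.len;
    if (x.div != y.div) return x.div < y.div;
    if (x.start != y.start) return x.start < y.start;
    return x.fam < y.fam;
  });

  std::vector<char> covered(n, 0);
  auto free_span = [&](int s, int L) {
    for (int i = s; i < s + L; ++i) if (covered[i]) return false;
    return true;
  };
  auto mark = [&](int s, int L) {
    for (int i = s; i < s + L; ++i) covered[i] = 1;
  };

  std::vector<Cand> hits;
  std::deque<Cand> work;
  for (const auto &c : cands) {
    if (!free_span(c.start, c.len)) continue;
    mark(c.start, c.len);
    hits.push_back(c);
    work.push_back(c);
  }

  // tandem extension: try placements one monomer length to either side
  while (!work.empty()) {
    Cand h = work.front();
    work.pop_front();
    const std::string &m = cons[2 * h.fam + h.strand];
    for (int a : {h.start - h.len, h.start + h.len}) {
      if (a < 0 || a + h.len > n) continue;
      if (!free_span(a, h.len)) continue;
      double d = hamming_div(a, m);
      if (d <= max_divergence) {
        Cand nc{a, h.fam, h.strand, d, h.len};
        mark(a, h.len);
        hits.push_back(nc);
        work.push_back(nc);
      }
    }
  }

  std::sort(hits.begin(), hits.end(), [](const Cand &x, const Cand &y) {
    return x.start < y.start;
  });

  const int nh = (int)hits.size();
  IntegerVector start(nh), fam(nh), strand(nh);
  NumericVector div(nh);
  IntegerVector len(nh);
  for (int i = 0; i < nh; ++i) {
    start[i] = hits[i].start;
    fam[i] = hits[i].fam + 1;
    strand[i] = hits[i].strand;
    div[i] = hits[i].div;
    len[i] = hits[i].len;
  }
  return List::create(_["start"] = start, _["family"] = fam,
                      _["strand"] = strand, _["divergence"] = div,
                      _["length"] = len);
}
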