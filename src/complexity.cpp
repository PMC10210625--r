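#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;   // N or anything else
  }
}

// Linguistic complexity per window: observed k-mer vocabulary summed over
// k = 1..kmax, divided by the maximal possible vocabulary for a window of
// that length. k-mers touching an N are skipped; windows with >50% N are NA.
// [[Rcpp::export]]
NumericVector lc_scan_cpp(std::string seq, IntegerVector starts,
                          IntegerVector ends, int kmax) {
  const int n = seq.size();
  if (kmax < 1) stop("kmax must be >= 1");
  if (kmax > 12) stop("kmax must be <= 12");

  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);

  // stamp tables: one slab per k, epoch-stamped so no clearing between windows
  std::vector<long long> slab_off(kmax + 1, 0);
  long long tot = 0;
  std::vector<long long> pow4(kmax + 1, 1);
  for (int k = 1; k <= kmax; ++k) {
    pow4[k] = pow4[k - 1] * 4;
    slab_off[k] = tot;
    tot += pow4[k];
  }
  std::vector<int> stamp(tot, -1);

  const int nw = starts.size();
  NumericVector out(nw);
  for (int w = 0; w < nw; ++w) {
    const int s = starts[w], e = ends[w];
    const int L = e - s;
    if (L <= 0) { out[w] = NA_REAL; continue; }
    int nN = 0;
    for (int i = s; i < e; ++i) if (code[i] < 0) ++nN;
    if (2 * nN > L) { out[w] = NA_REAL; continue; }

    double denom = 0;
    for (int k = 1; k <= kmax; ++k) {
      long long cap = (long long)(L - k + 1);
      if (cap <= 0) break;
      denom += (double)std::min(pow4[k], cap);
    }
    if (denom <= 0) { out[w] = NA_REAL; continue; }

    // rolling codes for every k at once; validity via last invalid position
    std::vector<long long> kcode(kmax + 1, 0);
    long long vocab = 0;
    int last_bad = s - 1;
    const int epoch = w;
    for (int i = s; i < e; ++i) {
      const int c = code[i];
      if (c < 0) { last_bad = i; continue; }
      for (int k = 1; k <= kmax; ++k) {
        kcode[k] = (kcode[k] * 4 + c) % pow4[k];
        if (i - last_bad >= k && i - s + 1 >= k) {
          long long idx = slab_off[k] + kcode[k];
          if (stamp[idx] != epoch) { stamp[idx] = epoch; ++vocab; }
        }
      }
    }
    out[w] = (double)vocab / denom;
  }
  return out;
}
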