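#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int base_code2(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// Tandem-repeat periodicity spectrum: for every k-mer occurring at least
// min_count times, gaps between consecutive occurrence starts are tallied.
// Returns an integer vector of counts for lags 1..max_lag.
// [[Rcpp::export]]
IntegerVector spectrum_cpp(std::string seq, int k, int max_lag, int min_count) {
  const int n = seq.size();
  if (k < 1 || k > 12) stop("k must be in [1, 12]");
  if (n <= k) stop("sequence shorter than k");
  if (max_lag < 1) stop("max_lag must be >= 1");

  const long long nk = 1LL << (2 * k);
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code2(seq[i]);

  std::vector<int> cnt(nk, 0);
  // pass 1: occurrence counts of each k-mer (N-containing skipped)
  {
    long long kc = 0;
    int last_bad = -1;
    for (int i = 0; i < n; ++i) {
      const int c = code[i];
      if (c < 0) { last_bad = i; continue; }
      kc = ((kc << 2) | c) & (nk - 1);
      if (i - last_bad >= k && i + 1 >= k) ++cnt[kc];
    }
  }
  // pass 2: tally consecutive-occurrence gaps for frequent k-mers
  std::vector<int> last(nk, -1);
  IntegerVector tally(max_lag);
  {
    long long kc = 0;
    int last_bad = -1;
    for (int i = 0; i < n; ++i) {
      const int c = code[i];
      if (c < 0) { last_bad = i; continue; }
      kc = ((kc << 2) | c) & (nk - 1);
      if (i - last_bad >= k && i + 1 >= k) {
        const int p = i - k + 1;   // start of this k-mer
        if (cnt[kc] >= min_count) {
          if (last[kc] >= 0) {
            const int lag = p - last[kc];
            if (lag >= 1 && lag <= max_lag) ++tally[lag - 1];
          }
          last[kc] = p;
        }
      }
    }
  }
  return tally;
}
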