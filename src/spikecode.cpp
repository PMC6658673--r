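#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Suffix array by rank doubling (O(n log^2 n)); adequate for ~1e6 binary symbols.
static std::vector<int> suffix_array(const IntegerVector& s) {
  int n = s.size();
  std::vector<int> sa(n), r(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; r[i] = s[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (r[a] != r[b]) return r[a] < r[b];
      int ra = a + k < n ? r[a + k] : -1;
      int rb = b + k < n ? r[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    for (int i = 0; i < n; ++i) r[i] = tmp[i];
    if (r[sa[n - 1]] == n - 1) break;
    if (k > n) break;
  }
  return sa;
}

// LZ76 exhaustive-history complexity c(n): number of phrases in the parsing
// where each phrase extends the longest factor already seen (occurrence
// starting strictly earlier, self-overlap allowed) by one fresh symbol; a
// trailing incomplete phrase counts. Computed via the longest-previous-factor
// array (suffix array + Kasai LCP + neighbour elimination), O(n log^2 n).
// [[Rcpp::export(.lz76_complexity_cpp)]]
int lz76_complexity_cpp(IntegerVector bits) {
  int n = bits.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  std::vector<int> sa = suffix_array(bits);
  std::vector<int> rank_(n), lcp(n, 0);
  for (int i = 0; i < n; ++i) rank_[sa[i]] = i;
  int h = 0;  // Kasai
  for (int i = 0; i < n; ++i) {
    if (rank_[i] > 0) {
      int j = sa[rank_[i] - 1];
      while (i + h < n && j + h < n && bits[i + h] == bits[j + h]) ++h;
      lcp[rank_[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  // LPF: process positions in decreasing order; active list then holds only
  // earlier positions, so neighbour LCPs bound matches with sources q < p.
  std::vector<int> prev(n), next(n), lcur(lcp), lpf(n, 0);
  for (int r = 0; r < n; ++r) { prev[r] = r - 1; next[r] = r + 1; }
  for (int p = n - 1; p >= 0; --p) {
    int r = rank_[p];
    int up = (prev[r] >= 0) ? lcur[r] : 0;
    int down = (next[r] < n) ? lcur[next[r]] : 0;
    lpf[p] = std::max(up, down);
    if (next[r] < n) {
      lcur[next[r]] = std::min(lcur[r], lcur[next[r]]);
      prev[next[r]] = prev[r];
    }
    if (prev[r] >= 0) next[prev[r]] = next[r];
  }
  int c = 0;
  long long p = 0;
  while (p < n) { ++c; p += (long long)lpf[p] + 1; }
  return c;
}

// Two-state Markov chain over {0,1}; start state supplied (drawn in R so all
// randomness flows through R's RNG / set.seed).
// [[Rcpp::export(.markov_bits_cpp)]]
IntegerVector markov_bits_cpp(int n, double p01, double p10, int start) {
  IntegerVector out(n);
  int s = start;
  out[0] = s;
  for (int i = 1; i < n; ++i) {
    double u = R::unif_rand();
    if (s == 0) s = (u < p01) ? 1 : 0;
    else        s = (u < p10) ? 0 : 1;
    out[i] = s;
  }
  return out;
}
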