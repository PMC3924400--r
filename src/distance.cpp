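#include "pms8_core.h"
using namespace Rcpp;

// [[Rcpp::export]]
int cpp_hamming(IntegerVector a, IntegerVector b) {
  if (a.size() != b.size()) stop("hamming distance requires equal lengths");
  return hamming_raw(INTEGER(a), INTEGER(b), a.size());
}

// tm: k x l matrix of codes, one tuple member per row
// [[Rcpp::export]]
int cpp_consensus_total_distance(IntegerMatrix tm, int sigma) {
  int k = tm.nrow(), l = tm.ncol();
  std::vector<int> cnt(sigma);
  int cd = 0;
  for (int col = 0; col < l; ++col) {
    std::fill(cnt.begin(), cnt.end(), 0);
    int mx = 0;
    for (int r = 0; r < k; ++r) {
      int c = ++cnt[tm(r, col)];
      if (c > mx) mx = c;
    }
    cd += k - mx;
  }
  return cd;
}

// Columnwise majority string; ties broken by lowest symbol code.
// [[Rcpp::export]]
IntegerVector cpp_consensus_string(IntegerMatrix tm, int sigma) {
  int k = tm.nrow(), l = tm.ncol();
  IntegerVector out(l);
  std::vector<int> cnt(sigma);
  for (int col = 0; col < l; ++col) {
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int r = 0; r < k; ++r) ++cnt[tm(r, col)];
    int best = 0;
    for (int s = 1; s < sigma; ++s) if (cnt[s] > cnt[best]) best = s;
    out[col] = best;
  }
  return out;
}
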