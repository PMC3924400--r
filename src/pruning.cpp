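#include "pms8_core.h"
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_column_type_counts(IntegerVector a, IntegerVector b,
                                     IntegerVector c) {
  int l = a.size();
  if (b.size() != l || c.size() != l) stop("column typing requires equal lengths");
  IntegerVector n(5);
  for (int k = 0; k < l; ++k) ++n[column_type(a[k], b[k], c[k])];
  return n;
}

// [[Rcpp::export]]
bool cpp_triple_condition(IntegerVector a, IntegerVector b, IntegerVector c,
                          IntegerVector bud) {
  int l = a.size();
  if (b.size() != l || c.size() != l) stop("triple test requires equal lengths");
  if (bud.size() != 3) stop("three budgets required");
  return triple_condition_raw(INTEGER(a), INTEGER(b), INTEGER(c), l, INTEGER(bud));
}

bool construct_neighbor3(const int* a, const int* b, const int* c,
                         int l, const int* bud, std::vector<int>& M) {
  if (!triple_condition_raw(a, b, c, l, bud)) return false;
  std::vector<int> type(l);
  int n[5] = {0, 0, 0, 0, 0};
  for (int k = 0; k < l; ++k) {
    type[k] = column_type(a[k], b[k], c[k]);
    ++n[type[k]];
  }
  const int* T[3] = {a, b, c};
  M.assign(l, 0);
  // Case 1: some member has at least d_i columns where it is the odd one
  // out; copy that member and repair d_i such columns (leftmost first) to
  // the symbol the other two share.
  for (int i = 0; i < 3; ++i) {
    if (n[i + 1] >= bud[i]) {
      for (int k = 0; k < l; ++k) M[k] = T[i][k];
      int left = bud[i];
      for (int k = 0; k < l && left > 0; ++k) {
        if (type[k] == i + 1) {
          // the two members other than i agree in an N_{i+1} column
          M[k] = (i == 0) ? b[k] : a[k];
          --left;
        }
      }
      return true;
    }
  }
  // Case 2: all n_i < d_i. Take the first member's symbol on N0/N2/N3
  // columns and the shared symbol on N1 columns; hand each member i its own
  // symbol in max(0, n_i + n4 - d_i) all-distinct columns (leftmost unused,
  // member order 1,2,3); remaining N4 columns default to the first member.
  int need[3];
  for (int i = 0; i < 3; ++i) {
    need[i] = n[i + 1] + n[4] - bud[i];
    if (need[i] < 0) need[i] = 0;
  }
  for (int k = 0; k < l; ++k) {
    switch (type[k]) {
    case 1: M[k] = b[k]; break;
    case 4:
      if (need[0] > 0)      { M[k] = a[k]; --need[0]; }
      else if (need[1] > 0) { M[k] = b[k]; --need[1]; }
      else if (need[2] > 0) { M[k] = c[k]; --need[2]; }
      else M[k] = a[k];
      break;
    default: M[k] = a[k];
    }
  }
  return true;
}

// [[Rcpp::export]]
SEXP cpp_construct_common_neighbor(IntegerVector a, IntegerVector b,
                                   IntegerVector c, IntegerVector bud) {
  int l = a.size();
  if (b.size() != l || c.size() != l) stop("triple test requires equal lengths");
  if (bud.size() != 3) stop("three budgets required");
  std::vector<int> M;
  if (!construct_neighbor3(INTEGER(a), INTEGER(b), INTEGER(c), l, INTEGER(bud), M))
    return R_NilValue;
  return wrap(M);
}

// Lemma-style necessary condition for any tuple size: consensus total
// distance within the summed budgets.
// [[Rcpp::export]]
bool cpp_tuple_condition(IntegerMatrix tm, IntegerVector bud, int sigma) {
  int k = tm.nrow(), l = tm.ncol();
  if (bud.size() != k) stop("one budget per tuple member required");
  int tot = 0;
  for (int i = 0; i < k; ++i) tot += bud[i];
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
    if (cd > tot) return false;
  }
  return true;
}
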