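#ifndef PMS8_CORE_H
#define PMS8_CORE_H

#include <Rcpp.h>
#include <vector>
#include <set>
#include <cstdint>

// l-mers are vectors of integer symbol codes in [0, sigma).
typedef std::vector<int> Lmer;

inline int hamming_raw(const int* a, const int* b, int l) {
  int d = 0;
  for (int k = 0; k < l; ++k) d += (a[k] != b[k]);
  return d;
}

// Hamming distance with early abort once the count exceeds `cap`.
inline int hamming_capped(const int* a, const int* b, int l, int cap) {
  int d = 0;
  for (int k = 0; k < l; ++k) {
    d += (a[k] != b[k]);
    if (d > cap) return d;
  }
  return d;
}

// Consensus total distance of a 3-tuple: per column 0 if all agree,
// 1 if exactly two agree, 2 if all distinct. Early abort above `cap`.
inline int cd3_capped(const int* a, const int* b, const int* c, int l, int cap) {
  int cd = 0;
  for (int k = 0; k < l; ++k) {
    if (a[k] == b[k]) {
      if (a[k] != c[k]) cd += 1;
    } else {
      cd += (a[k] == c[k] || b[k] == c[k]) ? 1 : 2;
    }
    if (cd > cap) return cd;
  }
  return cd;
}

// Column types for a 3-tuple: 0 all equal; 1 first differs; 2 second differs;
// 3 third differs; 4 all distinct.
inline int column_type(int x, int y, int z) {
  if (x == y) return (y == z) ? 0 : 3;
  if (y == z) return 1;
  if (x == z) return 2;
  return 4;
}

// Necessary-and-sufficient existence test for a common neighbor of three
// l-mers under per-member budgets: all pairwise Hamming distances within the
// summed budgets and consensus total distance within the total budget.
inline bool triple_condition_raw(const int* a, const int* b, const int* c,
                                 int l, const int* bud) {
  int b01 = bud[0] + bud[1], b02 = bud[0] + bud[2], b12 = bud[1] + bud[2];
  if (hamming_capped(a, b, l, b01) > b01) return false;
  if (hamming_capped(a, c, l, b02) > b02) return false;
  if (hamming_capped(b, c, l, b12) > b12) return false;
  int tot = bud[0] + bud[1] + bud[2];
  return cd3_capped(a, b, c, l, tot) <= tot;
}

// Constructive half of the triple test: returns false when no common
// neighbor exists, otherwise fills M with a witness meeting every budget.
bool construct_neighbor3(const int* a, const int* b, const int* c,
                         int l, const int* bud, std::vector<int>& M);

// Pruned depth-first enumeration of the common neighborhood of a k-tuple.
// T holds k row pointers to l codes each. Emits members in lexicographic
// code order via `emit`.
void gen_common_neighborhood(const std::vector<const int*>& T, int l,
                             const std::vector<int>& bud, int sigma,
                             bool prune,
                             const std::function<void(const std::vector<int>&)>& emit);

#endif
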