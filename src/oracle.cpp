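#include "pms8_core.h"
using namespace Rcpp;

namespace {

// Enumerate the Hamming ball of radius d around `base`, each member once
// (decide per position whether to keep or substitute).
void ball_rec(const int* base, int l, int sigma, int pos, int rem,
              std::vector<int>& cur, std::set<Lmer>& out) {
  if (pos == l) { out.insert(cur); return; }
  cur[pos] = base[pos];
  ball_rec(base, l, sigma, pos + 1, rem, cur, out);
  if (rem > 0) {
    for (int c = 0; c < sigma; ++c) {
      if (c == base[pos]) continue;
      cur[pos] = c;
      ball_rec(base, l, sigma, pos + 1, rem - 1, cur, out);
    }
    cur[pos] = base[pos];
  }
}

bool occurs_within(const Lmer& M, const std::vector<int>& seq, int l, int d) {
  int m = (int)seq.size();
  for (int off = 0; off + l <= m; ++off)
    if (hamming_capped(M.data(), seq.data() + off, l, d) <= d) return true;
  return false;
}

// Odometer scan of all sigma^l strings; true as soon as one string meets
// every budget.
bool exists_scan(const std::vector<const int*>& T, int k, int l,
                 const int* bud, int sigma) {
  std::vector<int> cur(l, 0);
  for (;;) {
    bool ok = true;
    for (int i = 0; i < k; ++i)
      if (hamming_capped(cur.data(), T[i], l, bud[i]) > bud[i]) { ok = false; break; }
    if (ok) return true;
    int pos = l - 1;
    while (pos >= 0 && cur[pos] == sigma - 1) cur[pos--] = 0;
    if (pos < 0) return false;
    ++cur[pos];
  }
}

} // namespace

// Reference pattern-driven search, independent of the pruned engine: union
// of the d-balls of the first sequence's windows, each candidate verified
// against every sequence by direct scanning.
// [[Rcpp::export]]
IntegerMatrix cpp_brute_force(List seqs, int l, int d, int sigma) {
  int n = seqs.size();
  std::vector<std::vector<int>> S(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = seqs[i];
    S[i].assign(v.begin(), v.end());
    if ((int)S[i].size() < l) stop("sequence shorter than l");
  }
  std::set<Lmer> cands;
  std::vector<int> cur(l, 0);
  int m0 = (int)S[0].size();
  for (int off = 0; off + l <= m0; ++off)
    ball_rec(S[0].data() + off, l, sigma, 0, d, cur, cands);
  std::set<Lmer> out;
  for (std::set<Lmer>::const_iterator it = cands.begin(); it != cands.end(); ++it) {
    bool ok = true;
    for (int i = 0; i < n; ++i)
      if (!occurs_within(*it, S[i], l, d)) { ok = false; break; }
    if (ok) out.insert(*it);
  }
  IntegerMatrix mm(out.size(), l);
  int r = 0;
  for (std::set<Lmer>::const_iterator it = out.begin(); it != out.end(); ++it, ++r)
    for (int j = 0; j < l; ++j) mm(r, j) = (*it)[j];
  return mm;
}

// [[Rcpp::export]]
bool cpp_exists_common_neighbor(IntegerMatrix tm, IntegerVector bud, int sigma) {
  int k = tm.nrow(), l = tm.ncol();
  if (bud.size() != k) stop("one budget per tuple member required");
  if (std::pow((double)sigma, l) > 2e7)
    stop("exhaustive scan cap exceeded (sigma^l too large)");
  std::vector<std::vector<int>> rows(k, std::vector<int>(l));
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < l; ++j) rows[i][j] = tm(i, j);
  std::vector<const int*> T(k);
  for (int i = 0; i < k; ++i) T[i] = rows[i].data();
  return exists_scan(T, k, l, INTEGER(bud), sigma);
}

// Full sweep of the triple test at l = 3: every triple of 3-mers over the
// alphabet, every budget vector in {0..dmax}^3, compared against the
// exhaustive scan; constructed witnesses are distance-checked.
// Returns (cases, condition-true cases, disagreements, witness failures).
// [[Rcpp::export]]
NumericVector cpp_theorem1_exhaustive_l3(int sigma, int dmax) {
  const int l = 3;
  int nl = sigma * sigma * sigma;  // number of 3-mers = candidates
  std::vector<std::vector<int>> mers(nl, std::vector<int>(l));
  for (int id = 0; id < nl; ++id) {
    int v = id;
    for (int j = l - 1; j >= 0; --j) { mers[id][j] = v % sigma; v /= sigma; }
  }
  double cases = 0, cond_true = 0, disagree = 0, witness_fail = 0;
  std::vector<int> d1(nl), d2(nl), d3(nl);
  std::vector<int> M;
  for (int i1 = 0; i1 < nl; ++i1) {
    const int* a = mers[i1].data();
    for (int i2 = 0; i2 < nl; ++i2) {
      const int* b = mers[i2].data();
      for (int i3 = 0; i3 < nl; ++i3) {
        const int* c = mers[i3].data();
        for (int id = 0; id < nl; ++id) {
          d1[id] = hamming_raw(mers[id].data(), a, l);
          d2[id] = hamming_raw(mers[id].data(), b, l);
          d3[id] = hamming_raw(mers[id].data(), c, l);
        }
        int bud[3];
        for (bud[0] = 0; bud[0] <= dmax; ++bud[0])
          for (bud[1] = 0; bud[1] <= dmax; ++bud[1])
            for (bud[2] = 0; bud[2] <= dmax; ++bud[2]) {
              cases += 1;
              bool exh = false;
              for (int id = 0; id < nl; ++id)
                if (d1[id] <= bud[0] && d2[id] <= bud[1] && d3[id] <= bud[2]) {
                  exh = true;
                  break;
                }
              bool cond = triple_condition_raw(a, b, c, l, bud);
              if (cond != exh) { disagree += 1; continue; }
              if (cond) {
                cond_true += 1;
                if (!construct_neighbor3(a, b, c, l, bud, M) ||
                    hamming_raw(M.data(), a, l) > bud[0] ||
                    hamming_raw(M.data(), b, l) > bud[1] ||
                    hamming_raw(M.data(), c, l) > bud[2])
                  witness_fail += 1;
              }
            }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return NumericVector::create(cases, cond_true, disagree, witness_fail);
}

// Randomized sweep: ncases random triples with l drawn in [lmin, lmax] and
// uniform budgets in {0..l}, triple test vs exhaustive scan plus witness
// verification. Uses R's RNG. Returns (cases, condition-true,
// disagreements, witness failures).
// [[Rcpp::export]]
NumericVector cpp_theorem1_random_check(int ncases, int lmin, int lmax,
                                        int sigma) {
  double cond_true = 0, disagree = 0, witness_fail = 0;
  std::vector<int> M;
  for (int cs = 0; cs < ncases; ++cs) {
    int l = lmin + (int)(unif_rand() * (lmax - lmin + 1));
    if (l > lmax) l = lmax;
    std::vector<int> a(l), b(l), c(l);
    for (int j = 0; j < l; ++j) {
      a[j] = (int)(unif_rand() * sigma) % sigma;
      b[j] = (int)(unif_rand() * sigma) % sigma;
      c[j] = (int)(unif_rand() * sigma) % sigma;
    }
    int bud[3];
    for (int i = 0; i < 3; ++i) bud[i] = (int)(unif_rand() * (l + 1)) % (l + 1);
    bool cond = triple_condition_raw(a.data(), b.data(), c.data(), l, bud);
    std::vector<const int*> T(3);
    T[0] = a.data(); T[1] = b.data(); T[2] = c.data();
    bool exh = exists_scan(T, 3, l, bud, sigma);
    if (cond != exh) { disagree += 1; continue; }
    if (cond) {
      cond_true += 1;
      if (!construct_neighbor3(a.data(), b.data(), c.data(), l, bud, M) ||
          hamming_raw(M.data(), a.data(), l) > bud[0] ||
          hamming_raw(M.data(), b.data(), l) > bud[1] ||
          hamming_raw(M.data(), c.data(), l) > bud[2])
        witness_fail += 1;
    }
    if (cs % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return NumericVector::create((double)ncases, cond_true, disagree, witness_fail);
}
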