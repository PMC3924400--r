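#include "pms8_core.h"
using namespace Rcpp;

namespace {

// Bits per symbol and symbols per 16-bit chunk for the packed l-mer table.
inline int bits_for(int sigma) {
  int b = 1;
  while ((1 << b) < sigma) ++b;
  return b;
}

// Lookup table: for every 16-bit value, the number of nonzero groups of
// `bits` bits. XOR of two packed chunks has a nonzero group exactly where
// the symbols differ, so one lookup scores a whole chunk.
std::vector<uint8_t> group_count_table(int bits, int cw) {
  std::vector<uint8_t> tab(1 << 16);
  int mask = (1 << bits) - 1;
  for (int v = 0; v < (1 << 16); ++v) {
    int c = 0;
    for (int g = 0; g < cw; ++g)
      if ((v >> (g * bits)) & mask) ++c;
    tab[v] = (uint8_t)c;
  }
  return tab;
}

struct Engine {
  int n = 0, l = 0, d = 0, sigma = 0;
  int stop_depth = 0, np = 0;
  bool sort_rows = true, use_pair = true, use_pack = true, minimal = false;
  std::vector<std::vector<int>> S;   // symbol codes per sequence
  std::vector<int> nwin, gbase;
  int totwin = 0;
  // packed chunks
  int bits = 0, cw = 0;
  std::vector<std::vector<uint16_t>> P;
  std::vector<uint8_t> tab;
  // cross-sequence pair compatibility (distance <= 2d)
  std::vector<uint64_t> mask;
  bool have_mask = false;
  // candidate matrix: all snapshots share one buffer per row; only row
  // sizes are stacked, filtered-out items are parked past the active prefix
  std::vector<std::vector<int>> rows;
  std::vector<int> rsz;
  std::vector<char> consumed;
  std::vector<std::vector<int>> size_stack;
  // tuple stack and incremental column counts for the Lemma-style bound
  std::vector<std::pair<int, int>> stk;
  std::vector<int> colcnt;  // l * sigma
  std::vector<int> colmax;  // l
  std::set<Lmer> motifs;
  double tuples = 0, neighborhoods = 0, verified = 0;

  int dist(int si, int oi, int sj, int oj) const {
    if (use_pack) {
      int k = 0, dd = 0;
      const uint16_t* pi = P[si].data() + oi;
      const uint16_t* pj = P[sj].data() + oj;
      for (; k + cw <= l; k += cw) dd += tab[pi[k] ^ pj[k]];
      const int* a = S[si].data() + oi;
      const int* b = S[sj].data() + oj;
      for (; k < l; ++k) dd += (a[k] != b[k]);
      return dd;
    }
    return hamming_raw(S[si].data() + oi, S[sj].data() + oj, l);
  }

  bool pair_ok(int si, int oi, int sj, int oj) const {
    if (have_mask) {
      size_t bit = (size_t)(gbase[si] + oi) * totwin + (gbase[sj] + oj);
      return (mask[bit >> 6] >> (bit & 63)) & 1;
    }
    return dist(si, oi, sj, oj) <= 2 * d;
  }

  void build_pack() {
    bits = bits_for(sigma);
    cw = 16 / bits;
    if (cw < 1) cw = 1;
    tab = group_count_table(bits, cw);
    P.assign(n, std::vector<uint16_t>());
    for (int i = 0; i < n; ++i) {
      int m = (int)S[i].size();
      int npos = m - cw + 1;
      if (npos < 0) npos = 0;
      P[i].assign(npos, 0);
      for (int j = 0; j < npos; ++j) {
        uint16_t v = 0;
        for (int g = 0; g < cw; ++g)
          v |= (uint16_t)(S[i][j + g] << (g * bits));
        P[i][j] = v;
      }
    }
  }

  void build_mask() {
    double nbits = (double)totwin * totwin;
    if (nbits > 4e9) { have_mask = false; return; }  // cap ~0.5 GB
    mask.assign(((size_t)totwin * totwin + 63) / 64, 0);
    for (int si = 0; si < n; ++si)
      for (int sj = si + 1; sj < n; ++sj)
        for (int oi = 0; oi < nwin[si]; ++oi)
          for (int oj = 0; oj < nwin[sj]; ++oj)
            if (dist(si, oi, sj, oj) <= 2 * d) {
              size_t b1 = (size_t)(gbase[si] + oi) * totwin + (gbase[sj] + oj);
              size_t b2 = (size_t)(gbase[sj] + oj) * totwin + (gbase[si] + oi);
              mask[b1 >> 6] |= (uint64_t)1 << (b1 & 63);
              mask[b2 >> 6] |= (uint64_t)1 << (b2 & 63);
            }
    have_mask = true;
  }

  // keep u = (ru, off) after pushing x = stack top?
  bool keep(int ru, int off) const {
    int sx = stk.back().first, ox = stk.back().second;
    if (!pair_ok(ru, off, sx, ox)) return false;
    int depth = (int)stk.size();
    const int* uu = S[ru].data() + off;
    const int* xx = S[sx].data() + ox;
    if (minimal) {
      // literal filter: pair bound with the new top plus, right after the
      // second push, the exact triple test with the first two items
      if (depth == 2) {
        const int* r1 = S[stk[0].first].data() + stk[0].second;
        int bud[3] = {d, d, d};
        if (!triple_condition_raw(r1, xx, uu, l, bud)) return false;
      }
      return true;
    }
    // strong filter: exact triple test against every stack item below the
    // top, then the consensus-distance bound on stack + u
    for (int i = 0; i + 1 < depth; ++i) {
      int si = stk[i].first, oi = stk[i].second;
      if (!pair_ok(ru, off, si, oi)) return false;
      const int* ri = S[si].data() + oi;
      // pairwise parts with x already hold; the remaining triple content is
      // the consensus bound (pair (ri,x) holds by stack invariant)
      if (cd3_capped(ri, xx, uu, l, 3 * d) > 3 * d) return false;
    }
    if (depth >= 2) {
      int k = depth;
      int cap = (k + 1) * d;
      int cd = 0;
      for (int c = 0; c < l; ++c) {
        int cu = colcnt[c * sigma + uu[c]] + 1;
        int mx = colmax[c] > cu ? colmax[c] : cu;
        cd += (k + 1) - mx;
        if (cd > cap) return false;
      }
    }
    return true;
  }

  void col_push(const int* x) {
    for (int c = 0; c < l; ++c) {
      int v = ++colcnt[c * sigma + x[c]];
      if (v > colmax[c]) colmax[c] = v;
    }
  }

  void col_pop(const int* x) {
    for (int c = 0; c < l; ++c) {
      --colcnt[c * sigma + x[c]];
      int mx = 0;
      for (int s = 0; s < sigma; ++s) {
        int v = colcnt[c * sigma + s];
        if (v > mx) mx = v;
      }
      colmax[c] = mx;
    }
  }

  // push x and filter every unconsumed active row in place; on any row
  // running empty, restore and report failure
  bool push_and_filter(int sx, int ox) {
    stk.push_back(std::make_pair(sx, ox));
    col_push(S[sx].data() + ox);
    size_stack.push_back(rsz);
    bool ok = true;
    for (int r = 0; r < np && ok; ++r) {
      if (consumed[r]) continue;
      std::vector<int>& row = rows[r];
      int w = 0;
      for (int idx = 0; idx < rsz[r]; ++idx) {
        if (keep(r, row[idx])) {
          std::swap(row[w], row[idx]);
          ++w;
        }
      }
      rsz[r] = w;
      if (w == 0) ok = false;
    }
    if (!ok) { pop_state(); return false; }
    return true;
  }

  void pop_state() {
    rsz = size_stack.back();
    size_stack.pop_back();
    col_pop(S[stk.back().first].data() + stk.back().second);
    stk.pop_back();
  }

  int next_row() const {
    int best = -1;
    for (int r = 0; r < np; ++r) {
      if (consumed[r]) continue;
      if (best < 0) best = r;
      else if (sort_rows && rsz[r] < rsz[best]) best = r;
    }
    return best;
  }

  int dist_to_window(const Lmer& M, int si, int off) const {
    return hamming_capped(M.data(), S[si].data() + off, l, d);
  }

  bool row_has_witness(const Lmer& M, int r) const {
    for (int idx = 0; idx < rsz[r]; ++idx)
      if (dist_to_window(M, r, rows[r][idx]) <= d) return true;
    return false;
  }

  bool seq_has_witness(const Lmer& M, int r) const {
    for (int off = 0; off < nwin[r]; ++off)
      if (dist_to_window(M, r, off) <= d) return true;
    return false;
  }

  void emit() {
    neighborhoods += 1;
    int k = (int)stk.size();
    std::vector<const int*> T(k);
    for (int i = 0; i < k; ++i)
      T[i] = S[stk[i].first].data() + stk[i].second;
    std::vector<int> bud(k, d);
    gen_common_neighborhood(T, l, bud, sigma, true, [&](const Lmer& M) {
      verified += 1;
      // unconsumed active rows: the filtered candidates suffice, because a
      // witness of a common neighbor of the stack always survives the filter
      for (int r = 0; r < np; ++r)
        if (!consumed[r] && !row_has_witness(M, r)) return;
      // held-out sequences: full scan
      for (int r = np; r < n; ++r)
        if (!seq_has_witness(M, r)) return;
      motifs.insert(M);
    });
  }

  void explore() {
    tuples += 1;
    if ((int)stk.size() >= stop_depth) { emit(); return; }
    // the first sequence always anchors the search (one subproblem per
    // window of sequence 1); later rows follow the configured order
    int r = stk.empty() ? 0 : next_row();
    if (r < 0) { emit(); return; }
    consumed[r] = 1;
    for (int idx = 0; idx < rsz[r]; ++idx) {
      int off = rows[r][idx];
      if (push_and_filter(r, off)) {
        explore();
        pop_state();
      }
    }
    consumed[r] = 0;
  }
};

} // namespace

// Core search. seqs: list of integer code vectors; t and nprime must be
// resolved (clamped) by the caller; first_offsets0: 0-based window offsets
// of the first sequence to anchor on (the parallel jobs restrict this).
// [[Rcpp::export]]
List cpp_pms8_search(List seqs, int l, int d, int sigma, int t, int nprime,
                     bool sort_rows, bool pair_table, bool packing,
                     bool minimal_filter, IntegerVector first_offsets0) {
  Engine e;
  e.n = seqs.size();
  e.l = l; e.d = d; e.sigma = sigma;
  e.sort_rows = sort_rows; e.use_pack = packing; e.minimal = minimal_filter;
  e.S.resize(e.n);
  e.nwin.resize(e.n);
  e.gbase.resize(e.n);
  int g = 0;
  for (int i = 0; i < e.n; ++i) {
    IntegerVector v = seqs[i];
    e.S[i].assign(v.begin(), v.end());
    int m = (int)e.S[i].size();
    if (m < l) stop("sequence shorter than l");
    e.nwin[i] = m - l + 1;
    e.gbase[i] = g;
    g += e.nwin[i];
  }
  e.totwin = g;
  if (nprime < 1) nprime = 1;
  if (nprime > e.n) nprime = e.n;
  e.np = nprime;
  if (t < 1) t = 1;
  e.stop_depth = t < nprime ? t : nprime;
  if (e.use_pack) e.build_pack();
  if (pair_table) e.build_mask();
  e.rows.assign(e.n, std::vector<int>());
  e.rsz.assign(e.n, 0);
  for (int i = 0; i < e.n; ++i) {
    if (i == 0) {
      e.rows[0].assign(first_offsets0.begin(), first_offsets0.end());
      for (size_t j = 0; j < e.rows[0].size(); ++j)
        if (e.rows[0][j] < 0 || e.rows[0][j] >= e.nwin[0])
          stop("first-row offset out of range");
    } else {
      e.rows[i].resize(e.nwin[i]);
      for (int j = 0; j < e.nwin[i]; ++j) e.rows[i][j] = j;
    }
    e.rsz[i] = (int)e.rows[i].size();
  }
  e.consumed.assign(e.n, 0);
  e.colcnt.assign((size_t)l * sigma, 0);
  e.colmax.assign(l, 0);
  if (e.rsz[0] > 0) e.explore();
  IntegerMatrix mm(e.motifs.size(), l);
  int r = 0;
  for (std::set<Lmer>::const_iterator it = e.motifs.begin();
       it != e.motifs.end(); ++it, ++r)
    for (int j = 0; j < l; ++j) mm(r, j) = (*it)[j];
  return List::create(
    _["motifs"] = mm,
    _["tuples_explored"] = e.tuples,
    _["neighborhoods_generated"] = e.neighborhoods,
    _["candidates_verified"] = e.verified);
}

// [[Rcpp::export]]
bool cpp_verify_motif(IntegerVector M, List seqs, int d, int from_row0) {
  int l = M.size();
  Lmer mv(M.begin(), M.end());
  for (int i = from_row0; i < seqs.size(); ++i) {
    IntegerVector v = seqs[i];
    int m = v.size();
    if (m < l) return false;
    bool found = false;
    for (int off = 0; off + l <= m; ++off)
      if (hamming_capped(mv.data(), INTEGER(v) + off, l, d) <= d) {
        found = true;
        break;
      }
    if (!found) return false;
  }
  return true;
}

// Packed l-mer table for the R-level surface: per-position 16-bit chunks
// plus the group-count lookup.
// [[Rcpp::export]]
List cpp_pack_all_lmers(List seqs, int l, int sigma) {
  int bits = bits_for(sigma);
  int cw = 16 / bits;
  if (cw < 1) cw = 1;
  int n = seqs.size();
  List packed(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = seqs[i];
    int m = v.size();
    if (m < l) stop("sequence shorter than l");
    int npos = m - cw + 1;
    if (npos < 0) npos = 0;
    IntegerVector p(npos);
    for (int j = 0; j < npos; ++j) {
      int val = 0;
      for (int gix = 0; gix < cw; ++gix) val |= v[j + gix] << (gix * bits);
      p[j] = val;
    }
    packed[i] = p;
  }
  return List::create(_["chunk_width"] = cw, _["bits"] = bits,
                      _["packed"] = packed);
}

// [[Rcpp::export]]
int cpp_packed_distance(List packed, List seqs, int l, int cw, int bits,
                        int si, int oi, int sj, int oj) {
  IntegerVector pi = packed[si], pj = packed[sj];
  IntegerVector a = seqs[si], b = seqs[sj];
  if (oi < 0 || oi + l > a.size() || oj < 0 || oj + l > b.size())
    stop("window reference out of range");
  int mask = (1 << bits) - 1;
  int k = 0, dd = 0;
  for (; k + cw <= l; k += cw) {
    int x = pi[oi + k] ^ pj[oj + k];
    for (int gix = 0; gix < cw; ++gix)
      if ((x >> (gix * bits)) & mask) ++dd;
  }
  for (; k < l; ++k) dd += (a[oi + k] != b[oj + k]);
  return dd;
}
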