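#include "pms8_core.h"
using namespace Rcpp;

namespace {

struct NbrCtx {
  const std::vector<const int*>* T;
  int k, l, sigma;
  const std::vector<int>* bud;
  int budsum;
  bool prune;
  // suffix statistics: consensus total distance of columns [pos, l) and
  // pairwise suffix Hamming distances, indexed pos = 0..l
  std::vector<int> suffix_cd;                 // l + 1
  std::vector<std::vector<int>> suffix_pair;  // k*k entries of length l + 1
  std::vector<int> prefix;
  std::vector<int> h;
  const std::function<void(const std::vector<int>&)>* emit;
};

void nbr_dfs(NbrCtx& ctx, int pos) {
  const std::vector<const int*>& T = *ctx.T;
  const std::vector<int>& bud = *ctx.bud;
  int k = ctx.k;
  for (int c = 0; c < ctx.sigma; ++c) {
    int hsum = 0;
    bool ok = true;
    std::vector<int> h2(k);
    for (int i = 0; i < k; ++i) {
      h2[i] = ctx.h[i] + (c != T[i][pos]);
      hsum += h2[i];
      if (ctx.prune && h2[i] > bud[i]) { ok = false; break; }
    }
    if (!ok) continue;
    if (ctx.prune) {
      // tuple bound on the uncommitted columns
      if (hsum + ctx.suffix_cd[pos + 1] > ctx.budsum) continue;
      // pairwise bound on the uncommitted columns
      for (int i = 0; i < k && ok; ++i)
        for (int j = i + 1; j < k; ++j)
          if (h2[i] + h2[j] + ctx.suffix_pair[i * k + j][pos + 1] >
              bud[i] + bud[j]) { ok = false; break; }
      if (!ok) continue;
    }
    ctx.prefix[pos] = c;
    if (pos + 1 == ctx.l) {
      if (!ctx.prune) {
        bool leaf_ok = true;
        for (int i = 0; i < k; ++i) if (h2[i] > bud[i]) { leaf_ok = false; break; }
        if (!leaf_ok) continue;
      }
      (*ctx.emit)(ctx.prefix);
    } else {
      std::swap(ctx.h, h2);
      nbr_dfs(ctx, pos + 1);
      std::swap(ctx.h, h2);
    }
  }
}

} // namespace

void gen_common_neighborhood(const std::vector<const int*>& T, int l,
                             const std::vector<int>& bud, int sigma,
                             bool prune,
                             const std::function<void(const std::vector<int>&)>& emit) {
  int k = (int)T.size();
  NbrCtx ctx;
  ctx.T = &T; ctx.k = k; ctx.l = l; ctx.sigma = sigma;
  ctx.bud = &bud; ctx.prune = prune; ctx.emit = &emit;
  ctx.budsum = 0;
  for (int i = 0; i < k; ++i) ctx.budsum += bud[i];
  ctx.suffix_cd.assign(l + 1, 0);
  std::vector<int> cnt(sigma);
  for (int pos = l - 1; pos >= 0; --pos) {
    std::fill(cnt.begin(), cnt.end(), 0);
    int mx = 0;
    for (int i = 0; i < k; ++i) {
      int c = ++cnt[T[i][pos]];
      if (c > mx) mx = c;
    }
    ctx.suffix_cd[pos] = ctx.suffix_cd[pos + 1] + (k - mx);
  }
  ctx.suffix_pair.assign(k * k, std::vector<int>());
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j) {
      std::vector<int>& sp = ctx.suffix_pair[i * k + j];
      sp.assign(l + 1, 0);
      for (int pos = l - 1; pos >= 0; --pos)
        sp[pos] = sp[pos + 1] + (T[i][pos] != T[j][pos]);
    }
  ctx.prefix.assign(l, 0);
  ctx.h.assign(k, 0);
  if (l > 0) nbr_dfs(ctx, 0);
}

// tm: k x l tuple matrix. Returns the common neighborhood as a matrix with
// one member per row, rows in lexicographic code order.
// [[Rcpp::export]]
IntegerMatrix cpp_generate_common_neighborhood(IntegerMatrix tm,
                                               IntegerVector bud,
                                               int sigma, bool prune) {
  int k = tm.nrow(), l = tm.ncol();
  if (k < 1) stop("at least one tuple member required");
  if (bud.size() != k) stop("one budget per tuple member required");
  std::vector<std::vector<int>> rows(k, std::vector<int>(l));
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < l; ++j) rows[i][j] = tm(i, j);
  std::vector<const int*> T(k);
  for (int i = 0; i < k; ++i) T[i] = rows[i].data();
  std::vector<int> budv(bud.begin(), bud.end());
  std::vector<std::vector<int>> out;
  gen_common_neighborhood(T, l, budv, sigma, prune,
                          [&](const std::vector<int>& m) { out.push_back(m); });
  IntegerMatrix res(out.size(), l);
  for (size_t i = 0; i < out.size(); ++i)
    for (int j = 0; j < l; ++j) res(i, j) = out[i][j];
  return res;
}
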