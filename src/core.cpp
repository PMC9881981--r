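#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------- hashing ---

// splitmix64 finalizer: invertible mixing of packed k-mer codes, so minimizer
// selection is pseudo-random but fully deterministic.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// truncate to 52 bits so the hash is exactly representable as a double
static inline double hash_code(uint64_t code) {
  return (double)(mix64(code) >> 12);
}

// ------------------------------------------------------------- minimizers ---

struct Mini { int pos; double h; };

// every k-mer position that attains the minimum hash of at least one window
// of w consecutive k-mers is a minimizer (ties emit all positions)
static void get_minimizers(const int* s, int n, int k, int w, int asize,
                           std::vector<Mini>& out) {
  out.clear();
  if (n < k || k < 1 || w < 1) return;
  int nk = n - k + 1;
  std::vector<double> hs((size_t)nk, R_PosInf);
  uint64_t mod = 1;
  for (int i = 0; i < k; i++) mod *= (uint64_t)asize;
  uint64_t top = mod / (uint64_t)asize;
  uint64_t code = 0;
  int bad_until = -1;
  for (int i = 0; i < n; i++) {
    int c = s[i];
    if (c < 0 || c >= asize) { bad_until = i; code = 0; continue; }
    code = (code % top) * (uint64_t)asize + (uint64_t)c;
    if (i >= k - 1 && i - bad_until >= k) hs[i - k + 1] = hash_code(code);
  }
  int W = std::min(w, nk);
  std::vector<char> is_min((size_t)nk, 0);
  for (int j = 0; j + W <= nk; j++) {
    double m = R_PosInf;
    for (int x = j; x < j + W; x++) m = std::min(m, hs[x]);
    if (!R_FINITE(m)) continue;
    for (int x = j; x < j + W; x++) if (hs[x] == m) is_min[x] = 1;
  }
  for (int x = 0; x < nk; x++) if (is_min[x]) out.push_back({x, hs[x]});
}

// [[Rcpp::export]]
List cpp_minimizers(IntegerVector s, int k, int w, int asize) {
  std::vector<Mini> mm;
  get_minimizers(s.begin(), s.size(), k, w, asize, mm);
  IntegerVector pos(mm.size());
  NumericVector h(mm.size());
  for (size_t i = 0; i < mm.size(); i++) { pos[i] = mm[i].pos; h[i] = mm[i].h; }
  return List::create(_["pos"] = pos, _["hash"] = h);
}

// [[Rcpp::export]]
List cpp_build_index(List targets, int k, int w, int asize) {
  struct Ent { double h; int pos; int tid; };
  std::vector<Ent> ents;
  std::vector<Mini> mm;
  for (int t = 0; t < targets.size(); t++) {
    IntegerVector s = targets[t];
    get_minimizers(s.begin(), s.size(), k, w, asize, mm);
    for (auto& m : mm) ents.push_back({m.h, m.pos, t});
  }
  std::sort(ents.begin(), ents.end(), [](const Ent& a, const Ent& b) {
    if (a.h != b.h) return a.h < b.h;
    if (a.tid != b.tid) return a.tid < b.tid;
    return a.pos < b.pos;
  });
  NumericVector h(ents.size());
  IntegerVector pos(ents.size()), tid(ents.size());
  for (size_t i = 0; i < ents.size(); i++) {
    h[i] = ents[i].h; pos[i] = ents[i].pos; tid[i] = ents[i].tid;
  }
  return List::create(_["hash"] = h, _["pos"] = pos, _["tid"] = tid);
}

// ---------------------------------------------------------------- chaining --

struct ChainHit { std::vector<int> idx; double score; };

static inline double link_penalty(int dq, int dt, double cap) {
  int gd = std::abs(dq - dt);
  double p = 0.01 * (double)gd + 0.5 * std::log2((double)gd + 1.0);
  return std::min(p, cap);
}

// anchors sorted by (grp, tpos, qpos); chains must stay within one grp and be
// strictly increasing in both coordinates; score = #anchors - sum(penalty).
// `exact_rounds` re-runs the DP after removing each extracted chain (exact
// secondary chains, used by the exported chaining operation); the fast path
// computes the DP once and peels chains off it (the best chain is exact,
// secondaries are truncated at shared anchors).
static void chain_impl(const std::vector<int>& qp, const std::vector<int>& tp,
                       const std::vector<int>& grp,
                       int max_gap, double cap, int lookback,
                       int min_anchors, double min_score, int max_chains,
                       bool exact_rounds, std::vector<ChainHit>& chains) {
  chains.clear();
  int n = (int)qp.size();
  if (n == 0) return;
  std::vector<char> used((size_t)n, 0);
  std::vector<double> dp((size_t)n, 1.0);
  std::vector<int> par((size_t)n, -1);
  auto run_dp = [&]() {
    for (int i = 0; i < n; i++) {
      dp[i] = 1.0; par[i] = -1;
      if (used[i]) continue;
      int cnt = 0;
      for (int j = i - 1; j >= 0 && cnt < lookback; j--) {
        if (used[j]) continue;
        if (grp[j] != grp[i]) break;
        if (tp[i] - tp[j] > max_gap) break;
        cnt++;
        if (tp[j] >= tp[i] || qp[j] >= qp[i]) continue;
        int dq = qp[i] - qp[j];
        if (dq > max_gap) continue;
        double cand = dp[j] + 1.0 - link_penalty(dq, tp[i] - tp[j], cap);
        if (cand > dp[i]) { dp[i] = cand; par[i] = j; }
      }
    }
  };
  if (exact_rounds) {
    for (int round = 0; round < max_chains; round++) {
      run_dp();
      double best = -1e18; int bi = -1;
      for (int i = 0; i < n; i++) {
        if (!used[i] && dp[i] > best) { best = dp[i]; bi = i; }
      }
      if (bi < 0 || best < min_score) break;
      ChainHit ch; ch.score = best;
      for (int x = bi; x >= 0; x = par[x]) { ch.idx.push_back(x); used[x] = 1; }
      std::reverse(ch.idx.begin(), ch.idx.end());
      if ((int)ch.idx.size() >= min_anchors) chains.push_back(std::move(ch));
    }
  } else {
    run_dp();
    std::vector<int> order(n);
    for (int i = 0; i < n; i++) order[i] = i;
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return dp[a] > dp[b]; });
    for (int oi = 0; oi < n && (int)chains.size() < max_chains; oi++) {
      int bi = order[oi];
      if (used[bi]) continue;
      double base = 0;
      std::vector<int> idx;
      int x = bi;
      while (x >= 0 && !used[x]) { idx.push_back(x); x = par[x]; }
      if (x >= 0) base = dp[x]; // truncated at an anchor of a better chain
      double sc = dp[bi] - base;
      if (sc < min_score) continue;
      for (int y : idx) used[y] = 1;
      if ((int)idx.size() < min_anchors) continue;
      ChainHit ch; ch.score = sc;
      ch.idx.assign(idx.rbegin(), idx.rend());
      chains.push_back(std::move(ch));
    }
  }
  std::sort(chains.begin(), chains.end(),
            [](const ChainHit& a, const ChainHit& b) { return a.score > b.score; });
}

// [[Rcpp::export]]
List cpp_chain(IntegerVector qpos, IntegerVector tpos, IntegerVector grp,
               int max_gap, double gap_cap, int lookback,
               int min_anchors, double min_score, int max_chains) {
  std::vector<int> qp(qpos.begin(), qpos.end()), tp(tpos.begin(), tpos.end()),
      gg(grp.begin(), grp.end());
  std::vector<ChainHit> chains;
  chain_impl(qp, tp, gg, max_gap, gap_cap, lookback, min_anchors, min_score,
             max_chains, true, chains);
  List out(chains.size());
  for (size_t c = 0; c < chains.size(); c++) {
    IntegerVector idx(chains[c].idx.size());
    for (size_t i = 0; i < chains[c].idx.size(); i++) idx[i] = chains[c].idx[i] + 1;
    out[c] = List::create(_["idx"] = idx, _["score"] = chains[c].score);
  }
  return out;
}

// ----------------------------------------------------------- affine gap DP --

struct AP { double ma, mi, go, ge; };

static inline double subsc(const AP& ap, int a, int b) {
  return (a >= 0 && a == b) ? ap.ma : ap.mi;
}

struct Ops {
  std::vector<std::pair<char, int>> v;
  void push(char op, int len) {
    if (len <= 0) return;
    if (!v.empty() && v.back().first == op) v.back().second += len;
    else v.push_back({op, len});
  }
  void append(const Ops& o) { for (auto& p : o.v) push(p.first, p.second); }
};

static const double NEG = -1e18;

// crude instrumentation counters (read back via cpp_perf_counters)
static long g_dp_calls = 0, g_dp_cells = 0, g_ext_calls = 0, g_ext_cells = 0;

// [[Rcpp::export]]
NumericVector cpp_perf_counters(bool reset = false) {
  NumericVector out = NumericVector::create(
    (double)g_dp_calls, (double)g_dp_cells, (double)g_ext_calls,
    (double)g_ext_cells);
  if (reset) { g_dp_calls = g_dp_cells = g_ext_calls = g_ext_cells = 0; }
  return out;
}

// banded global affine alignment of q[0..lq) vs t[0..lt) with traceback.
// When `shifted`, the band follows the corner-to-corner diagonal (always
// connects); otherwise it sits on the main diagonal and may fail to reach the
// far corner. Returns false when the result was band-constrained; the caller
// may widen and retry.
static bool affine_global(const int* q, int lq, const int* t, int lt,
                          const AP& ap, int band, bool shifted, Ops& ops,
                          double& score, int& nm, int& matches) {
  score = 0; nm = 0; matches = 0;
  if (lq == 0 && lt == 0) return true;
  if (lq == 0) { ops.push('D', lt); score = ap.go + ap.ge * lt; nm = lt; return true; }
  if (lt == 0) { ops.push('I', lq); score = ap.go + ap.ge * lq; nm = lq; return true; }
  int dmin = shifted ? std::min(0, lt - lq) : 0;
  int dmax = shifted ? std::max(0, lt - lq) : 0;
  if (!shifted && std::abs(lt - lq) > band) return false; // corner unreachable
  int width = dmax - dmin + 2 * band + 1;
  size_t cells = (size_t)(lq + 1) * (size_t)width;
  if (cells > (size_t)96e6) {
    // too large even banded: crude fill, flagged as band-limited
    int m = std::min(lq, lt);
    ops.push('M', m);
    double s = 0; int mm = 0;
    for (int i = 0; i < m; i++) {
      s += subsc(ap, q[i], t[i]);
      if (q[i] >= 0 && q[i] == t[i]) matches++; else mm++;
    }
    if (lq > m) { ops.push('I', lq - m); s += ap.go + ap.ge * (lq - m); mm += lq - m; }
    if (lt > m) { ops.push('D', lt - m); s += ap.go + ap.ge * (lt - m); mm += lt - m; }
    score = s; nm = mm;
    return false;
  }
  auto lo_of = [&](int i) { return std::max(0, i + dmin - band); };
  auto hi_of = [&](int i) { return std::min(lt, i + dmax + band); };
  // reusable scratch: this DP runs once per inter-anchor gap, so allocation
  // cost would otherwise dominate on small gaps
  static thread_local std::vector<double> M0, X0, Y0, M1, X1, Y1;
  static thread_local std::vector<uint8_t> tb;
  M0.assign(lt + 1, NEG); X0.assign(lt + 1, NEG); Y0.assign(lt + 1, NEG);
  M1.assign(lt + 1, NEG); X1.assign(lt + 1, NEG); Y1.assign(lt + 1, NEG);
  // tb bits: 0-1 M-from(state at diag), 2-3 X-from(state above), 4-5 Y-from(state left)
  tb.assign(cells, 0);
  auto tbi = [&](int i, int j) { return (size_t)i * width + (size_t)(j - (i + dmin - band)); };
  M0[0] = 0;
  for (int j = std::max(1, lo_of(0)); j <= hi_of(0); j++) {
    double fromM = (j == 1) ? M0[0] + ap.go + ap.ge : NEG;
    double fromY = (j >= 2 && Y0[j - 1] > NEG / 2) ? Y0[j - 1] + ap.ge : NEG;
    if (fromM >= fromY) { Y0[j] = fromM; tb[tbi(0, j)] |= (0 << 4); }
    else { Y0[j] = fromY; tb[tbi(0, j)] |= (2 << 4); }
  }
  for (int i = 1; i <= lq; i++) {
    int lo = lo_of(i), hi = hi_of(i);
    int plo = lo_of(i - 1), phi = hi_of(i - 1);
    std::fill(M1.begin() + lo, M1.begin() + hi + 1, NEG);
    std::fill(X1.begin() + lo, X1.begin() + hi + 1, NEG);
    std::fill(Y1.begin() + lo, Y1.begin() + hi + 1, NEG);
    for (int j = lo; j <= hi; j++) {
      uint8_t& T = tb[tbi(i, j)];
      if (j >= 1 && j - 1 >= plo && j - 1 <= phi) {
        double dm = M0[j - 1], dx = X0[j - 1], dy = Y0[j - 1];
        int st = 0; double b = dm;
        if (dx > b) { b = dx; st = 1; }
        if (dy > b) { b = dy; st = 2; }
        if (b > NEG / 2) { M1[j] = b + subsc(ap, q[i - 1], t[j - 1]); T |= st; }
      }
      if (j >= plo && j <= phi) {
        double om = (M0[j] > NEG / 2) ? M0[j] + ap.go + ap.ge : NEG;
        double ox = (X0[j] > NEG / 2) ? X0[j] + ap.ge : NEG;
        double oy = (Y0[j] > NEG / 2) ? Y0[j] + ap.go + ap.ge : NEG;
        int st = 0; double b = om;
        if (ox > b) { b = ox; st = 1; }
        if (oy > b) { b = oy; st = 2; }
        if (b > NEG / 2) { X1[j] = b; T |= (st << 2); }
      }
      if (j - 1 >= lo) {
        double om = (M1[j - 1] > NEG / 2) ? M1[j - 1] + ap.go + ap.ge : NEG;
        double ox = (X1[j - 1] > NEG / 2) ? X1[j - 1] + ap.go + ap.ge : NEG;
        double oy = (Y1[j - 1] > NEG / 2) ? Y1[j - 1] + ap.ge : NEG;
        int st = 0; double b = om;
        if (ox > b) { b = ox; st = 1; }
        if (oy > b) { b = oy; st = 2; }
        if (b > NEG / 2) { Y1[j] = b; T |= (st << 4); }
      }
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  int st = 0; double b = M0[lt];
  if (X0[lt] > b) { b = X0[lt]; st = 1; }
  if (Y0[lt] > b) { b = Y0[lt]; st = 2; }
  if (b < NEG / 2) return false;
  score = b;
  // traceback
  bool hit = false;
  std::vector<std::pair<char, int>> rev;
  int i = lq, j = lt;
  while (i > 0 || j > 0) {
    int lo = lo_of(i), hi = hi_of(i);
    if ((j == lo && lo > 0) || (j == hi && hi < lt)) hit = true;
    uint8_t T = tb[tbi(i, j)];
    if (st == 0) {
      if (q[i - 1] >= 0 && q[i - 1] == t[j - 1]) matches++; else nm++;
      rev.push_back({'M', 1}); st = T & 3; i--; j--;
    } else if (st == 1) {
      nm++; rev.push_back({'I', 1}); st = (T >> 2) & 3; i--;
    } else {
      nm++; rev.push_back({'D', 1}); st = (T >> 4) & 3; j--;
    }
  }
  for (auto it = rev.rbegin(); it != rev.rend(); ++it) ops.push(it->first, it->second);
  return !hit;
}

// x-drop extension from (0,0): align prefixes of q against prefixes of t,
// maximizing score over match-state cells; adaptive band around the running
// best column. Emits consumed lengths and ops (in forward order).
static void affine_extend(const int* q, int lq, const int* t, int lt,
                          const AP& ap, int band, double zdrop, double slack,
                          Ops& ops, double& score, int& oql, int& otl, int& nm) {
  score = 0; oql = 0; otl = 0; nm = 0;
  if (lq == 0 || lt == 0) return;
  int width = 2 * band + 1;
  static thread_local std::vector<double> M0, X0, Y0, M1, X1, Y1;
  static thread_local std::vector<int> row_lo;
  static thread_local std::vector<uint8_t> tb;
  M0.assign(lt + 1, NEG); X0.assign(lt + 1, NEG); Y0.assign(lt + 1, NEG);
  M1.assign(lt + 1, NEG); X1.assign(lt + 1, NEG); Y1.assign(lt + 1, NEG);
  row_lo.clear();
  tb.clear();
  row_lo.reserve(lq + 1);
  int center = 0;
  M0[0] = 0;
  int lo0 = 0, hi0 = std::min(lt, band);
  row_lo.push_back(0);
  tb.resize((size_t)width, 0);
  for (int j = 1; j <= hi0; j++) {
    double fromM = (j == 1) ? ap.go + ap.ge : NEG;
    double fromY = (Y0[j - 1] > NEG / 2) ? Y0[j - 1] + ap.ge : NEG;
    if (fromM >= fromY) { Y0[j] = fromM; tb[(size_t)j] |= (0 << 4); }
    else { Y0[j] = fromY; tb[(size_t)j] |= (2 << 4); }
  }
  double gbest = 0; int gi = 0, gj = 0;
  static thread_local std::vector<double> rowbestM;
  static thread_local std::vector<int> rowbestj;
  rowbestM.assign((size_t)lq + 1, NEG);
  rowbestj.assign((size_t)lq + 1, 0);
  rowbestM[0] = 0;
  int last_row = 0;
  int plo = lo0, phi = hi0;
  for (int i = 1; i <= lq; i++) {
    int lo = std::max(0, center - band), hi = std::min(lt, center + band);
    if (lo > phi + 1) break; // band disconnected
    row_lo.push_back(lo);
    tb.resize((size_t)(i + 1) * width, 0);
    std::fill(M1.begin() + lo, M1.begin() + hi + 1, NEG);
    std::fill(X1.begin() + lo, X1.begin() + hi + 1, NEG);
    std::fill(Y1.begin() + lo, Y1.begin() + hi + 1, NEG);
    double rbest = NEG; int rbj = lo;
    for (int j = lo; j <= hi; j++) {
      uint8_t& T = tb[(size_t)i * width + (size_t)(j - lo)];
      if (j >= 1 && j - 1 >= plo && j - 1 <= phi) {
        double dm = M0[j - 1], dx = X0[j - 1], dy = Y0[j - 1];
        int st = 0; double b = dm;
        if (dx > b) { b = dx; st = 1; }
        if (dy > b) { b = dy; st = 2; }
        if (b > NEG / 2) { M1[j] = b + subsc(ap, q[i - 1], t[j - 1]); T |= st; }
      }
      if (j >= plo && j <= phi) {
        double om = (M0[j] > NEG / 2) ? M0[j] + ap.go + ap.ge : NEG;
        double ox = (X0[j] > NEG / 2) ? X0[j] + ap.ge : NEG;
        int st = 0; double b = om;
        if (ox > b) { b = ox; st = 1; }
        if (b > NEG / 2) { X1[j] = b; T |= (st << 2); }
      }
      if (j - 1 >= lo) {
        double om = (M1[j - 1] > NEG / 2) ? M1[j - 1] + ap.go + ap.ge : NEG;
        double oy = (Y1[j - 1] > NEG / 2) ? Y1[j - 1] + ap.ge : NEG;
        int st = 0; double b = om;
        if (oy > b) { b = oy; st = 2; }
        if (b > NEG / 2) { Y1[j] = b; T |= (st << 4); }
      }
      double cellbest = std::max(M1[j], std::max(X1[j], Y1[j]));
      if (cellbest > rbest) { rbest = cellbest; rbj = j; }
      if (M1[j] > rowbestM[i]) { rowbestM[i] = M1[j]; rowbestj[i] = j; }
      if (M1[j] > gbest) { gbest = M1[j]; gi = i; gj = j; }
    }
    last_row = i;
    if (rbest < gbest - zdrop) break;
    center = rbj;
    plo = lo; phi = hi;
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  if (slack > 0) {
    // prefer the deepest extension whose score stays within `slack` of the
    // best: long noisy tails are kept aligned instead of soft-clipped
    for (int i = last_row; i > gi; i--) {
      if (rowbestM[i] >= gbest - slack) { gi = i; gj = rowbestj[i]; break; }
    }
  }
  if (gi == 0) return;
  // traceback from (gi, gj) in M state
  std::vector<std::pair<char, int>> rev;
  int i = gi, j = gj, st = 0;
  while (i > 0 || j > 0) {
    int lo = row_lo[(size_t)i];
    uint8_t T = tb[(size_t)i * width + (size_t)(j - lo)];
    if (st == 0) {
      if (!(q[i - 1] >= 0 && q[i - 1] == t[j - 1])) nm++;
      rev.push_back({'M', 1}); st = T & 3; i--; j--;
    } else if (st == 1) {
      nm++; rev.push_back({'I', 1}); st = (T >> 2) & 3; i--;
    } else {
      nm++; rev.push_back({'D', 1}); st = (T >> 4) & 3; j--;
    }
  }
  score = gbest; oql = gi; otl = gj;
  for (auto it = rev.rbegin(); it != rev.rend(); ++it) ops.push(it->first, it->second);
}

// ----------------------------------------------------- chain -> alignment ---

struct Seg {
  int qs, qe, ts, te;
  double score;
  int nm;
  Ops ops;
};

struct AlnParams {
  AP ap;
  int band_pad;
  double zdrop;
  int split_min;
  double split_frac;
  double split_ident;
  double ext_slack;
  bool do_ext;
  bool strict_band;
  int band; // used when strict_band
};

static std::string ops_to_cigar(const Ops& o) {
  std::string s;
  char buf[32];
  for (auto& p : o.v) { snprintf(buf, sizeof(buf), "%d%c", p.second, p.first); s += buf; }
  return s;
}

// returns true if all internal DPs stayed within their bands
static bool align_chain_impl(const int* q, int lq, const int* t, int wlo, int whi,
                             std::vector<int> aq, std::vector<int> at, int k,
                             const AlnParams& P, std::vector<Seg>& segs) {
  segs.clear();
  bool band_ok = true;
  if (aq.empty()) return true;
  // keep only anchors consistent with a clean walk (same diagonal, or clear
  // of the previous anchor in both coordinates)
  std::vector<int> fq, ft;
  fq.push_back(aq[0]); ft.push_back(at[0]);
  for (size_t i = 1; i < aq.size(); i++) {
    int pq = fq.back(), pt = ft.back();
    if (aq[i] <= pq || at[i] <= pt) continue;
    if (aq[i] - pq == at[i] - pt || (aq[i] >= pq + k && at[i] >= pt + k)) {
      fq.push_back(aq[i]); ft.push_back(at[i]);
    }
  }
  auto emitM = [&](Seg& sg, int from_q, int from_t, int len) {
    for (int x = 0; x < len; x++) {
      sg.score += subsc(P.ap, q[from_q + x], t[from_t + x]);
      if (!(q[from_q + x] >= 0 && q[from_q + x] == t[from_t + x])) sg.nm++;
    }
    sg.ops.push('M', len);
  };
  Seg cur; cur.qs = fq[0]; cur.ts = ft[0]; cur.score = 0; cur.nm = 0;
  emitM(cur, fq[0], ft[0], k);
  int cq = fq[0] + k, ct = ft[0] + k;
  for (size_t i = 1; i < fq.size(); i++) {
    int a = fq[i], b = ft[i];
    // exact same-diagonal step: plain M extension (also covers overlapping
    // anchors); any mismatch or length imbalance goes through the gap DP so
    // the emitted alignment is DP-optimal between anchors and a bad region
    // (e.g. an inverted segment) can still split the record
    if (a - cq == b - ct) {
      int d = a - cq;
      bool clean = d <= 64;
      for (int x = 0; clean && x < d; x++) {
        if (!(q[cq + x] >= 0 && q[cq + x] == t[ct + x])) clean = false;
      }
      if (clean) {
        int dd = a + k - cq;
        if (dd > 0) { emitM(cur, cq, ct, dd); cq += dd; ct += dd; }
        continue;
      }
    }
    int gq = a - cq, gt = b - ct; // both >= 0 by the anchor filter
    if (gq == 0) {
      cur.ops.push('D', gt); cur.score += P.ap.go + P.ap.ge * gt; cur.nm += gt;
    } else if (gt == 0) {
      cur.ops.push('I', gq); cur.score += P.ap.go + P.ap.ge * gq; cur.nm += gq;
    } else {
      Ops gops; double gs; int gnm, gmatch;
      // the drift of a noisy-but-homologous gap beyond its length imbalance
      // is tiny, so a slim band suffices (the shifted band always connects)
      int gband = P.strict_band ? P.band : std::abs(gq - gt) + 12;
      bool ok = affine_global(q + cq, gq, t + ct, gt, P.ap, gband, !P.strict_band,
                              gops, gs, gnm, gmatch);
      if (!ok) band_ok = false;
      if (gops.v.empty()) { // band could not connect the anchors: crude fill
        int m = std::min(gq, gt);
        gs = 0; gnm = 0; gmatch = 0;
        for (int x = 0; x < m; x++) {
          gs += subsc(P.ap, q[cq + x], t[ct + x]);
          if (q[cq + x] >= 0 && q[cq + x] == t[ct + x]) gmatch++; else gnm++;
        }
        gops.push('M', m);
        if (gq > m) { gops.push('I', gq - m); gs += P.ap.go + P.ap.ge * (gq - m); gnm += gq - m; }
        if (gt > m) { gops.push('D', gt - m); gs += P.ap.go + P.ap.ge * (gt - m); gnm += gt - m; }
      }
      // split only on roughly balanced bad gaps whose aligned portion is
      // below the identity expected of homologous sequence (an inverted or
      // foreign segment); a one-sided gap, or a gap whose matched part is
      // genuinely homologous (e.g. a deletion flanked by repeats), is a
      // structural indel and must stay inside the record as its I/D run
      bool split = (std::min(gq, gt) >= P.split_min) &&
                   (std::min(gq, gt) >= 0.25 * std::max(gq, gt)) &&
                   (gmatch < P.split_ident * std::min(gq, gt)) &&
                   (gs < -P.split_frac * (double)(gq + gt));
      if (split) {
        cur.qe = cq; cur.te = ct;
        segs.push_back(cur);
        cur = Seg(); cur.qs = a; cur.ts = b; cur.score = 0; cur.nm = 0;
      } else {
        cur.ops.append(gops); cur.score += gs; cur.nm += gnm;
      }
    }
    emitM(cur, a, b, k);
    cq = a + k; ct = b + k;
  }
  cur.qe = cq; cur.te = ct;
  segs.push_back(cur);
  if (P.do_ext && segs.size() > 1) {
    // extend the inner boundaries of split records toward each other: the
    // split leaves the junction inside an anchor desert (e.g. a tandem
    // array), and x-drop extension recovers the homologous part so the
    // reported breakpoints sit at the junction rather than the last anchor
    int eband = P.strict_band ? P.band : P.band_pad;
    for (size_t si2 = 0; si2 + 1 < segs.size(); si2++) {
      Seg& L = segs[si2];
      Seg& R = segs[si2 + 1];
      { // rightward from the left record
        int ql_av = R.qs - L.qe, tl_av = R.ts - L.te;
        if (ql_av > 0 && tl_av > 0) {
          Ops eops; double es; int eq, et, enm;
          affine_extend(q + L.qe, ql_av, t + L.te, tl_av, P.ap, eband,
                        P.zdrop, P.ext_slack, eops, es, eq, et, enm);
          if (eq > 0 && es > 0) {
            L.ops.append(eops);
            L.qe += eq; L.te += et; L.score += es; L.nm += enm;
          }
        }
      }
      { // leftward into the gap from the right record
        int ql_av = R.qs - L.qe, tl_av = R.ts - L.te;
        if (ql_av > 0 && tl_av > 0) {
          std::vector<int> rq((size_t)ql_av), rt((size_t)tl_av);
          for (int x = 0; x < ql_av; x++) rq[x] = q[R.qs - 1 - x];
          for (int x = 0; x < tl_av; x++) rt[x] = t[R.ts - 1 - x];
          Ops eops; double es; int eq, et, enm;
          affine_extend(rq.data(), ql_av, rt.data(), tl_av, P.ap, eband,
                        P.zdrop, P.ext_slack, eops, es, eq, et, enm);
          if (eq > 0 && es > 0) {
            std::reverse(eops.v.begin(), eops.v.end());
            Ops merged; merged.append(eops); merged.append(R.ops);
            R.ops = merged;
            R.qs -= eq; R.ts -= et; R.score += es; R.nm += enm;
          }
        }
      }
    }
  }
  // a split whose gap the inner extensions have almost closed was a local
  // noise burst, not a foreign segment: re-join it (a genuinely foreign
  // region, e.g. an inverted segment, resists extension and stays wide)
  if (segs.size() > 1) {
    std::vector<Seg> merged;
    merged.push_back(segs[0]);
    for (size_t si2 = 1; si2 < segs.size(); si2++) {
      Seg& L = merged.back();
      Seg& R = segs[si2];
      int gq = R.qs - L.qe, gt = R.ts - L.te;
      if (gq >= 0 && gt >= 0 && std::min(gq, gt) <= 120 &&
          std::max(gq, gt) <= 180) {
        Ops gops; double gs; int gnm, gmatch;
        int gband = std::abs(gq - gt) + 16;
        affine_global(q + L.qe, gq, t + L.te, gt, P.ap, gband, true,
                      gops, gs, gnm, gmatch);
        L.ops.append(gops);
        L.ops.append(R.ops);
        L.qe = R.qe; L.te = R.te;
        L.score += gs + R.score; L.nm += gnm + R.nm;
      } else {
        merged.push_back(R);
      }
    }
    segs = std::move(merged);
  }
  if (P.do_ext && !segs.empty()) {
    int eband = P.strict_band ? P.band : P.band_pad;
    { // left extension on the first segment
      Seg& sg = segs.front();
      int ql_av = sg.qs, tl_av = sg.ts - wlo;
      if (ql_av > 0 && tl_av > 0) {
        std::vector<int> rq((size_t)ql_av), rt((size_t)tl_av);
        for (int x = 0; x < ql_av; x++) rq[x] = q[sg.qs - 1 - x];
        for (int x = 0; x < tl_av; x++) rt[x] = t[sg.ts - 1 - x];
        Ops eops; double es; int eq, et, enm;
        affine_extend(rq.data(), ql_av, rt.data(), tl_av, P.ap, eband, P.zdrop,
                      P.ext_slack, eops, es, eq, et, enm);
        if (eq > 0) {
          std::reverse(eops.v.begin(), eops.v.end());
          Ops merged; merged.append(eops); merged.append(sg.ops);
          sg.ops = merged;
          sg.qs -= eq; sg.ts -= et; sg.score += es; sg.nm += enm;
        }
      }
    }
    { // right extension on the last segment
      Seg& sg = segs.back();
      int ql_av = lq - sg.qe, tl_av = whi - sg.te;
      if (ql_av > 0 && tl_av > 0) {
        Ops eops; double es; int eq, et, enm;
        affine_extend(q + sg.qe, ql_av, t + sg.te, tl_av, P.ap, eband, P.zdrop,
                      P.ext_slack, eops, es, eq, et, enm);
        if (eq > 0) {
          sg.ops.append(eops);
          sg.qe += eq; sg.te += et; sg.score += es; sg.nm += enm;
        }
      }
    }
  }
  return band_ok;
}

static AlnParams params_from_list(List par) {
  AlnParams P;
  P.ap.ma = as<double>(par["match"]);
  P.ap.mi = as<double>(par["mismatch"]);
  P.ap.go = as<double>(par["gap_open"]);
  P.ap.ge = as<double>(par["gap_ext"]);
  P.band_pad = as<int>(par["band_pad"]);
  P.zdrop = as<double>(par["zdrop"]);
  P.split_min = as<int>(par["split_min"]);
  P.split_frac = as<double>(par["split_frac"]);
  P.split_ident = par.containsElementNamed("split_ident") ?
      as<double>(par["split_ident"]) : 0.78;
  P.ext_slack = par.containsElementNamed("ext_slack") ?
      as<double>(par["ext_slack"]) : 50.0;
  P.do_ext = as<bool>(par["extend_ends"]);
  P.strict_band = par.containsElementNamed("band") && as<int>(par["band"]) > 0;
  P.band = P.strict_band ? as<int>(par["band"]) : 0;
  return P;
}

// [[Rcpp::export]]
List cpp_align_chain(IntegerVector q, IntegerVector t,
                     IntegerVector aq, IntegerVector at, int k, List par) {
  AlnParams P = params_from_list(par);
  std::vector<int> vq(aq.begin(), aq.end()), vt(at.begin(), at.end());
  std::vector<Seg> segs;
  bool ok = align_chain_impl(q.begin(), q.size(), t.begin(), 0, t.size(),
                             vq, vt, k, P, segs);
  int n = (int)segs.size();
  IntegerVector qs(n), qe(n), ts(n), te(n), nm(n);
  NumericVector sc(n);
  CharacterVector cig(n);
  for (int i = 0; i < n; i++) {
    qs[i] = segs[i].qs; qe[i] = segs[i].qe; ts[i] = segs[i].ts; te[i] = segs[i].te;
    nm[i] = segs[i].nm; sc[i] = segs[i].score; cig[i] = ops_to_cigar(segs[i].ops);
  }
  return List::create(_["qstart"] = qs, _["qend"] = qe, _["tstart"] = ts,
                      _["tend"] = te, _["score"] = sc, _["nm"] = nm,
                      _["cigar"] = cig, _["band_ok"] = ok);
}

// -------------------------------------------------------------- map query ---

struct Win { int tid, lo, hi; };

// [[Rcpp::export]]
List cpp_map_query(IntegerVector qf, Nullable<IntegerVector> qr_,
                   NumericVector idx_hash, IntegerVector idx_pos,
                   IntegerVector idx_tid, List targets,
                   int k, int w, int asize,
                   Nullable<List> windows_, List par) {
  AlnParams P = params_from_list(par);
  int max_gap = as<int>(par["max_gap"]);
  double gap_cap = as<double>(par["gap_cap"]);
  int lookback = as<int>(par["lookback"]);
  int max_occ = as<int>(par["max_occ"]);
  int min_anchors = as<int>(par["min_chain_anchors"]);
  double min_score = as<double>(par["min_chain_score"]);
  int max_chains = as<int>(par["max_chains"]);
  int min_new = as<int>(par["min_new"]);
  int min_seg = as<int>(par["min_seg"]);

  std::vector<Win> wins;
  if (windows_.isNotNull()) {
    List W(windows_);
    IntegerVector wt = W["tid"], wl = W["lo"], wh = W["hi"];
    for (int i = 0; i < wt.size(); i++) wins.push_back({wt[i], wl[i], wh[i]});
  }
  const double* H = idx_hash.begin();
  int nidx = idx_hash.size();

  struct OriAnch { std::vector<int> qp, tp, grp; };
  struct Cand {
    int ori, grp; double score; std::vector<int> aq, at; int tid, lo, hi;
  };
  std::vector<Cand> cands;

  int n_queries = qr_.isNotNull() ? 2 : 1;
  IntegerVector qr = qr_.isNotNull() ? IntegerVector(qr_) : IntegerVector(0);
  std::vector<Mini> mm;
  // a read lying wholly inside a tandem array has only high-occurrence
  // seeds; if the strict occurrence cap yields no chain at all, retry once
  // with a relaxed cap (the array is usually still a unique locus)
  for (int occ_round = 0; occ_round < 2 && cands.empty(); occ_round++) {
  int occ_cap = occ_round == 0 ? max_occ : std::min(max_occ * 16, 256);
  for (int o = 0; o < n_queries; o++) {
    IntegerVector& Qv = (o == 0) ? qf : qr;
    get_minimizers(Qv.begin(), Qv.size(), k, w, asize, mm);
    // collect anchors
    struct A { int grp, tp, qp; };
    std::vector<A> anch;
    for (auto& m : mm) {
      const double* lb = std::lower_bound(H, H + nidx, m.h);
      const double* ub = std::upper_bound(H, H + nidx, m.h);
      int cnt = (int)(ub - lb);
      if (cnt == 0 || cnt > occ_cap) continue;
      for (const double* p = lb; p < ub; p++) {
        int ii = (int)(p - H);
        int tp = idx_pos[ii], td = idx_tid[ii];
        int grp;
        if (wins.empty()) grp = td;
        else {
          grp = -1;
          for (size_t wi = 0; wi < wins.size(); wi++) {
            if (wins[wi].tid == td && tp >= wins[wi].lo && tp < wins[wi].hi) {
              grp = (int)wi; break;
            }
          }
          if (grp < 0) continue;
        }
        anch.push_back({grp, tp, m.pos});
      }
    }
    std::sort(anch.begin(), anch.end(), [](const A& a, const A& b) {
      if (a.grp != b.grp) return a.grp < b.grp;
      if (a.tp != b.tp) return a.tp < b.tp;
      return a.qp < b.qp;
    });
    std::vector<int> qp(anch.size()), tp(anch.size()), gg(anch.size());
    for (size_t i = 0; i < anch.size(); i++) {
      qp[i] = anch[i].qp; tp[i] = anch[i].tp; gg[i] = anch[i].grp;
    }
    std::vector<ChainHit> chains;
    chain_impl(qp, tp, gg, max_gap, gap_cap, lookback, min_anchors, min_score,
               max_chains, false, chains);
    for (auto& ch : chains) {
      Cand c; c.ori = o; c.score = ch.score;
      c.grp = gg[ch.idx[0]];
      for (int ix : ch.idx) { c.aq.push_back(qp[ix]); c.at.push_back(tp[ix]); }
      if (wins.empty()) { c.tid = c.grp; c.lo = 0; c.hi = Rf_length(targets[c.tid]); }
      else { c.tid = wins[c.grp].tid; c.lo = wins[c.grp].lo; c.hi = wins[c.grp].hi; }
      cands.push_back(std::move(c));
    }
  }
  } // occurrence-relaxation retry
  std::sort(cands.begin(), cands.end(),
            [](const Cand& a, const Cand& b) {
              if (a.score != b.score) return a.score > b.score;
              if (a.at.empty() || b.at.empty()) return a.at.size() > b.at.size();
              if (a.at[0] != b.at[0]) return a.at[0] < b.at[0];
              return a.tid < b.tid;
            });
  // drop near-duplicate chains (tandem-shifted copies of a better chain in
  // the same orientation); they waste the chain budget and starve
  // opposite-orientation candidates such as an inverted segment
  {
    std::vector<Cand> kept;
    for (auto& c : cands) {
      bool dup = false;
      int cqlo = c.aq.front(), cqhi = c.aq.back() + k;
      int ctlo = c.at.front(), cthi = c.at.back() + k;
      for (auto& d : kept) {
        if (d.ori != c.ori || d.tid != c.tid) continue;
        int dqlo = d.aq.front(), dqhi = d.aq.back() + k;
        int dtlo = d.at.front(), dthi = d.at.back() + k;
        int qo = std::min(cqhi, dqhi) - std::max(cqlo, dqlo);
        int to = std::min(cthi, dthi) - std::max(ctlo, dtlo);
        int qm2 = std::min(cqhi - cqlo, dqhi - dqlo);
        int tm2 = std::min(cthi - ctlo, dthi - dtlo);
        if (qm2 > 0 && tm2 > 0 && qo > 0.8 * qm2 && to > 0.8 * tm2) {
          dup = true; break;
        }
      }
      if (!dup) kept.push_back(std::move(c));
      if ((int)kept.size() >= max_chains) break;
    }
    cands = std::move(kept);
  }

  int Lq = qf.size();
  // chains summary (for ROI extraction)
  int nc = (int)cands.size();
  IntegerVector c_ori(nc), c_tid(nc), c_qlo(nc), c_qhi(nc), c_tlo(nc), c_thi(nc),
      c_na(nc);
  NumericVector c_sc(nc);
  for (int i = 0; i < nc; i++) {
    const Cand& c = cands[i];
    c_ori[i] = c.ori; c_tid[i] = c.tid;
    c_qlo[i] = c.aq.front(); c_qhi[i] = c.aq.back() + k;
    c_tlo[i] = c.at.front(); c_thi[i] = c.at.back() + k;
    c_sc[i] = c.score; c_na[i] = (int)c.aq.size();
  }

  // align chains in rank order with per-orientation query-coverage
  // selection: a region absorbed by one orientation may still align in the
  // other (the inverted-segment case), so coverage does not transfer
  std::vector<std::vector<char>> covered(2, std::vector<char>((size_t)Lq, 0));
  std::vector<int> r_ori, r_rank, r_tid, r_qs, r_qe, r_ts, r_te, r_nm, r_na;
  std::vector<double> r_sc, r_chsc, r_other;
  std::vector<std::string> r_cig;
  std::vector<Seg> segs;
  for (int ci = 0; ci < nc; ci++) {
    Cand& c = cands[ci];
    if (ci > 0) {
      // skip alignment of a chain whose query span adds nothing new
      int clo = c.aq.front(), chi = c.aq.back() + k;
      int os = (c.ori == 0) ? clo : Lq - chi;
      int oe = (c.ori == 0) ? chi : Lq - clo;
      os = std::max(os, 0); oe = std::min(oe, Lq);
      int fresh = 0;
      for (int x = os; x < oe; x++) if (!covered[c.ori][x]) fresh++;
      if (fresh < min_new) continue;
    }
    IntegerVector tgt = targets[c.tid];
    IntegerVector& Qv = (c.ori == 0) ? qf : qr;
    align_chain_impl(Qv.begin(), Qv.size(), tgt.begin(), c.lo, c.hi,
                     c.aq, c.at, k, P, segs);
    // second-best = best chain at a genuinely alternative locus (target
    // overlap below half of the shorter span); repeat-shifted chains over
    // the same locus do not make a hit ambiguous
    double other = 0;
    int ci_lo = c.at.front(), ci_hi = c.at.back() + k;
    for (int cj = 0; cj < nc; cj++) {
      if (cj == ci) continue;
      const Cand& d = cands[cj];
      int cj_lo = d.at.front(), cj_hi = d.at.back() + k;
      double ov = 0;
      if (d.tid == c.tid) {
        int o = std::min(ci_hi, cj_hi) - std::max(ci_lo, cj_lo);
        int m = std::min(ci_hi - ci_lo, cj_hi - cj_lo);
        if (m > 0 && o > 0) ov = (double)o / (double)m;
      }
      if (ov < 0.5) other = std::max(other, d.score);
    }
    for (auto& sg : segs) {
      if (sg.qe - sg.qs < min_seg && !(ci == 0 && segs.size() == 1)) continue;
      int os = (c.ori == 0) ? sg.qs : Lq - sg.qe;
      int oe = (c.ori == 0) ? sg.qe : Lq - sg.qs;
      int fresh = 0;
      for (int x = os; x < oe; x++) if (!covered[c.ori][x]) fresh++;
      if (ci > 0 && fresh < min_new) continue;
      if (ci == 0 || fresh >= min_new) {
        for (int x = os; x < oe; x++) covered[c.ori][x] = 1;
        r_ori.push_back(c.ori); r_rank.push_back(ci); r_tid.push_back(c.tid);
        r_qs.push_back(sg.qs); r_qe.push_back(sg.qe);
        r_ts.push_back(sg.ts); r_te.push_back(sg.te);
        r_sc.push_back(sg.score); r_nm.push_back(sg.nm);
        r_cig.push_back(ops_to_cigar(sg.ops));
        r_chsc.push_back(c.score); r_other.push_back(other);
        r_na.push_back((int)c.aq.size());
      }
    }
  }
  int nr = (int)r_ori.size();
  IntegerVector o_ori(nr), o_rank(nr), o_tid(nr), o_qs(nr), o_qe(nr), o_ts(nr),
      o_te(nr), o_nm(nr), o_na(nr);
  NumericVector o_sc(nr), o_chsc(nr), o_other(nr);
  CharacterVector o_cig(nr);
  for (int i = 0; i < nr; i++) {
    o_ori[i] = r_ori[i]; o_rank[i] = r_rank[i]; o_tid[i] = r_tid[i];
    o_qs[i] = r_qs[i]; o_qe[i] = r_qe[i]; o_ts[i] = r_ts[i]; o_te[i] = r_te[i];
    o_nm[i] = r_nm[i]; o_na[i] = r_na[i]; o_sc[i] = r_sc[i];
    o_chsc[i] = r_chsc[i]; o_other[i] = r_other[i]; o_cig[i] = r_cig[i];
  }
  return List::create(
    _["records"] = List::create(
      _["orient"] = o_ori, _["chain_rank"] = o_rank, _["tid"] = o_tid,
      _["qstart"] = o_qs, _["qend"] = o_qe, _["tstart"] = o_ts, _["tend"] = o_te,
      _["score"] = o_sc, _["nm"] = o_nm, _["cigar"] = o_cig,
      _["chain_score"] = o_chsc, _["best_other"] = o_other, _["n_anchors"] = o_na),
    _["chains"] = List::create(
      _["orient"] = c_ori, _["tid"] = c_tid, _["qlo"] = c_qlo, _["qhi"] = c_qhi,
      _["tlo"] = c_tlo, _["thi"] = c_thi, _["score"] = c_sc,
      _["n_anchors"] = c_na));
}

// ----------------------------------------------------------- edit distance --

// exact Levenshtein by banded DP with band doubling
// [[Rcpp::export]]
int cpp_edit_distance(IntegerVector a, IntegerVector b) {
  int la = a.size(), lb = b.size();
  if (la == 0) return lb;
  if (lb == 0) return la;
  const int* A = a.begin();
  const int* B = b.begin();
  int diff = std::abs(la - lb);
  int band = std::max(16, diff);
  const int BIG = INT_MAX / 4;
  while (true) {
    int dmin = std::min(0, lb - la), dmax = std::max(0, lb - la);
    std::vector<int> prev(lb + 1, BIG), curr(lb + 1, BIG);
    int lo0 = 0, hi0 = std::min(lb, dmax + band);
    for (int j = lo0; j <= hi0; j++) prev[j] = j;
    int plo = lo0, phi = hi0;
    for (int i = 1; i <= la; i++) {
      int lo = std::max(0, i + dmin - band), hi = std::min(lb, i + dmax + band);
      for (int j = lo; j <= hi; j++) curr[j] = BIG;
      if (lo == 0) curr[0] = i;
      for (int j = std::max(1, lo); j <= hi; j++) {
        int best = BIG;
        if (j - 1 >= plo && j - 1 <= phi && prev[j - 1] < BIG)
          best = prev[j - 1] + ((A[i - 1] == B[j - 1]) ? 0 : 1);
        if (j >= plo && j <= phi && prev[j] < BIG)
          best = std::min(best, prev[j] + 1);
        if (j - 1 >= lo && curr[j - 1] < BIG)
          best = std::min(best, curr[j - 1] + 1);
        curr[j] = best;
      }
      std::swap(prev, curr);
      plo = lo; phi = hi;
    }
    int d = prev[lb];
    if (d <= band || band >= la + lb) return d;
    band *= 2;
  }
}
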