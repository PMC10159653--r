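#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cstdint>
#include <memory>
#include <stdexcept>
#include <string>
#include <vector>

#include "cigar_util.h"

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Per-worker arena (bump) allocator: allocates incrementally from beginning
// to end, frees everything at once on reset. All offsets are 8-byte aligned
// so blocks are directly usable as DMA-style transfer units.
// ---------------------------------------------------------------------------

struct ArenaExhausted : public std::runtime_error {
  ArenaExhausted() : std::runtime_error("arena exhausted") {}
};

class Arena {
public:
  // uninitialized backing store: untouched pages are never committed, so
  // a large-capacity arena costs only what a pair actually allocates
  explicit Arena(std::size_t capacity)
      : buf_(new uint8_t[capacity]), cap_(capacity), cursor_(0), high_(0) {}
  std::size_t alloc(std::size_t nbytes) {
    if (nbytes == 0) throw std::invalid_argument("nbytes must be > 0");
    std::size_t rounded = (nbytes + 7u) & ~std::size_t(7);
    if (cursor_ + rounded > cap_) throw ArenaExhausted();
    std::size_t off = cursor_;
    cursor_ += rounded;
    high_ = std::max(high_, cursor_);
    return off;
  }
  void reset() { cursor_ = 0; }
  std::size_t capacity() const { return cap_; }
  std::size_t cursor() const { return cursor_; }
  std::size_t high_water() const { return high_; }
  int32_t *i32(std::size_t off) {
    return reinterpret_cast<int32_t *>(buf_.get() + off);
  }

private:
  std::unique_ptr<uint8_t[]> buf_;
  std::size_t cap_;
  std::size_t cursor_, high_;
};

// [[Rcpp::export(name = ".arena_new_cpp")]]
SEXP arena_new_cpp(double capacity) {
  if (capacity < 8) stop("arena capacity must be at least 8 bytes");
  XPtr<Arena> p(new Arena((std::size_t)capacity), true);
  return p;
}

// [[Rcpp::export(name = ".arena_alloc_cpp")]]
double arena_alloc_cpp(SEXP arena, double nbytes) {
  XPtr<Arena> p(arena);
  if (nbytes < 1) stop("nbytes must be positive");
  try {
    return (double)p->alloc((std::size_t)nbytes);
  } catch (ArenaExhausted &) {
    stop("arena exhausted: requested %.0f bytes with %.0f of %.0f in use",
         nbytes, (double)p->cursor(), (double)p->capacity());
  }
}

// [[Rcpp::export(name = ".arena_reset_cpp")]]
void arena_reset_cpp(SEXP arena) { XPtr<Arena>(arena)->reset(); }

// [[Rcpp::export(name = ".arena_stats_cpp")]]
NumericVector arena_stats_cpp(SEXP arena) {
  XPtr<Arena> p(arena);
  return NumericVector::create(_["capacity"] = (double)p->capacity(),
                               _["cursor"] = (double)p->cursor(),
                               _["high_water"] = (double)p->high_water());
}

// ---------------------------------------------------------------------------
// Gap-affine wavefront alignment with backtrace.
//
// Conventions: diagonal d = i - j (pattern index minus text index); the
// furthest-reaching offset stored per diagonal is i, the number of pattern
// characters consumed (so j = i - d). An insertion consumes pattern
// (d + 1), a deletion consumes text (d - 1). Match cost must be 0.
// All per-score offset arrays live in the worker's arena; wavefront
// history is retained in full for the backtrace.
// ---------------------------------------------------------------------------

static const int32_t WF_NULL = INT32_MIN / 2;

namespace {

struct WfComp {
  int lo = 0, hi = -1;     // component absent when lo > hi
  std::size_t off = 0;     // arena offset of int32 array of length hi-lo+1
  bool present() const { return lo <= hi; }
};

struct Wavefront {
  WfComp M, I, D;
};

struct WfView { // resolved accessor
  Arena *arena;
  int32_t get(const WfComp &c, int d) const {
    if (!c.present() || d < c.lo || d > c.hi) return WF_NULL;
    return arena->i32(c.off)[d - c.lo];
  }
};

} // namespace

struct WfaResult {
  bool success = false;
  int score = -1;
  bool pruned = false; // adaptive: did trimming ever remove a diagonal?
  std::string cigar;
  std::string reason;
};

static WfaResult wfa_core(const std::string &pattern, const std::string &text,
                          int x, int o, int e, bool adaptive, int min_wf_len,
                          int max_dist, Arena &arena) {
  WfaResult res;
  const int m = (int)pattern.size(), n = (int)text.size();
  const int dT = m - n; // terminal diagonal
  std::vector<Wavefront> wfs;
  WfView V{&arena};

  auto alloc_comp = [&](WfComp &c, int lo, int hi) {
    lo = std::max(lo, -n);
    hi = std::min(hi, m);
    if (lo > hi) { c.lo = 0; c.hi = -1; return; }
    c.lo = lo; c.hi = hi;
    c.off = arena.alloc((std::size_t)(hi - lo + 1) * sizeof(int32_t));
    int32_t *p = arena.i32(c.off);
    std::fill(p, p + (hi - lo + 1), WF_NULL);
  };

  auto extend = [&](WfComp &c) {
    if (!c.present()) return;
    int32_t *p = arena.i32(c.off);
    for (int d = c.lo; d <= c.hi; ++d) {
      int32_t i = p[d - c.lo];
      if (i == WF_NULL) continue;
      int j = i - d;
      while (i < m && j < n && pattern[i] == text[j]) { ++i; ++j; }
      p[d - c.lo] = i;
    }
  };

  auto reduce = [&](WfComp &c) { // adaptive trimming of outer diagonals
    if (!c.present() || c.hi - c.lo + 1 <= min_wf_len) return;
    const int old_lo = c.lo;
    const int32_t *p = arena.i32(c.off);
    long best = LONG_MIN;
    for (int d = c.lo; d <= c.hi; ++d) {
      int32_t i = p[d - old_lo];
      if (i != WF_NULL) best = std::max(best, 2L * i - d); // antidiag i + j
    }
    auto lag = [&](int d) {
      int32_t i = p[d - old_lo];
      return (i == WF_NULL) ? LONG_MAX : best - (2L * i - d);
    };
    const int old_hi = c.hi;
    while (c.lo < c.hi && lag(c.lo) > max_dist) ++c.lo;
    while (c.hi > c.lo && lag(c.hi) > max_dist) --c.hi;
    if (c.lo != old_lo || c.hi != old_hi) res.pruned = true;
    // rebase the stored-array origin so indexing by (d - lo) stays valid
    c.off += (std::size_t)(c.lo - old_lo) * sizeof(int32_t);
  };

  auto done = [&](const Wavefront &w) {
    return V.get(w.M, dT) >= m;
  };

  try {
    // s = 0
    wfs.emplace_back();
    alloc_comp(wfs[0].M, 0, 0);
    arena.i32(wfs[0].M.off)[0] = 0;
    extend(wfs[0].M);

    int s = 0;
    const long s_max = (long)x * std::min(m, n) + 2L * (o + e) +
                       (long)e * (std::abs(dT) + 2) + x + 1;
    while (!done(wfs[s])) {
      ++s;
      if (s > s_max) { res.reason = "no alignment found"; return res; }
      wfs.emplace_back();
      Wavefront &w = wfs[s];
      const Wavefront *wx = (s >= x) ? &wfs[s - x] : nullptr;
      const Wavefront *woe = (s >= o + e) ? &wfs[s - o - e] : nullptr;
      const Wavefront *we = (s >= e) ? &wfs[s - e] : nullptr;

      // I component: gap-open from M[s-o-e], gap-extend from I[s-e]
      {
        int lo = INT32_MAX, hi = INT32_MIN;
        if (woe && woe->M.present()) { lo = std::min(lo, woe->M.lo); hi = std::max(hi, woe->M.hi); }
        if (we && we->I.present()) { lo = std::min(lo, we->I.lo); hi = std::max(hi, we->I.hi); }
        if (lo <= hi) {
          alloc_comp(w.I, lo + 1, hi + 1);
          if (w.I.present()) {
            int32_t *p = arena.i32(w.I.off);
            for (int d = w.I.lo; d <= w.I.hi; ++d) {
              int32_t a = woe ? V.get(woe->M, d - 1) : WF_NULL;
              int32_t b = we ? V.get(we->I, d - 1) : WF_NULL;
              int32_t v = std::max(a, b);
              if (v == WF_NULL) continue;
              ++v; // consume one pattern character
              if (v > m || v - d < 0 || v - d > n) continue;
              p[d - w.I.lo] = v;
            }
          }
        }
      }
      // D component: gap-open from M[s-o-e], gap-extend from D[s-e]
      {
        int lo = INT32_MAX, hi = INT32_MIN;
        if (woe && woe->M.present()) { lo = std::min(lo, woe->M.lo); hi = std::max(hi, woe->M.hi); }
        if (we && we->D.present()) { lo = std::min(lo, we->D.lo); hi = std::max(hi, we->D.hi); }
        if (lo <= hi) {
          alloc_comp(w.D, lo - 1, hi - 1);
          if (w.D.present()) {
            int32_t *p = arena.i32(w.D.off);
            for (int d = w.D.lo; d <= w.D.hi; ++d) {
              int32_t a = woe ? V.get(woe->M, d + 1) : WF_NULL;
              int32_t b = we ? V.get(we->D, d + 1) : WF_NULL;
              int32_t v = std::max(a, b); // offset unchanged, one text char
              if (v == WF_NULL) continue;
              if (v > m || v - d < 0 || v - d > n) continue;
              p[d - w.D.lo] = v;
            }
          }
        }
      }
      // M component: mismatch from M[s-x], plus the new I and D
      {
        int lo = INT32_MAX, hi = INT32_MIN;
        if (wx && wx->M.present()) { lo = std::min(lo, wx->M.lo); hi = std::max(hi, wx->M.hi); }
        if (w.I.present()) { lo = std::min(lo, w.I.lo); hi = std::max(hi, w.I.hi); }
        if (w.D.present()) { lo = std::min(lo, w.D.lo); hi = std::max(hi, w.D.hi); }
        if (lo <= hi) {
          alloc_comp(w.M, lo, hi);
          if (w.M.present()) {
            int32_t *p = arena.i32(w.M.off);
            for (int d = w.M.lo; d <= w.M.hi; ++d) {
              int32_t mm = wx ? V.get(wx->M, d) : WF_NULL;
              if (mm != WF_NULL) {
                ++mm;
                if (mm > m || mm - d < 0 || mm - d > n) mm = WF_NULL;
              }
              int32_t v = std::max(mm, std::max(V.get(w.I, d), V.get(w.D, d)));
              if (v != WF_NULL) p[d - w.M.lo] = v;
            }
          }
        }
      }
      extend(w.M);
      if (done(w)) break;
      if (adaptive) reduce(w.M);
    }
    res.score = s;

    // ---- backtrace ------------------------------------------------------
    std::string ops;
    ops.reserve((std::size_t)m + n);
    int d = dT, i = m;
    char state = 'M';
    int sc = s;
    while (true) {
      if (state == 'M') {
        int32_t mism = WF_NULL, del = WF_NULL, ins = WF_NULL;
        if (sc >= x) {
          int32_t v = V.get(wfs[sc - x].M, d);
          if (v != WF_NULL && v + 1 <= i) mism = v + 1;
        }
        {
          int32_t v = V.get(wfs[sc].D, d);
          if (v != WF_NULL && v <= i) del = v;
          v = V.get(wfs[sc].I, d);
          if (v != WF_NULL && v <= i) ins = v;
        }
        int32_t v0 = std::max(mism, std::max(del, ins));
        if (v0 == WF_NULL) {
          ops.append((std::size_t)i, 'M'); // initial all-match run at s = 0
          break;
        }
        ops.append((std::size_t)(i - v0), 'M');
        if (mism == v0) { // prefer diagonal, then D, then I
          ops.push_back('X');
          sc -= x; i = v0 - 1;
        } else if (del == v0) {
          state = 'D'; i = v0;
        } else {
          state = 'I'; i = v0;
        }
      } else if (state == 'D') {
        ops.push_back('D');
        bool ext = sc >= e && V.get(wfs[sc - e].D, d + 1) == i;
        if (ext) { sc -= e; d += 1; }         // stay in gap (extension)
        else { sc -= o + e; d += 1; state = 'M'; }
      } else { // 'I'
        ops.push_back('I');
        bool ext = sc >= e && V.get(wfs[sc - e].I, d - 1) == i - 1;
        i -= 1;
        if (ext) { sc -= e; d -= 1; }
        else { sc -= o + e; d -= 1; state = 'M'; }
      }
    }
    std::reverse(ops.begin(), ops.end());
    res.cigar = rle_cigar(ops);
    res.success = true;
    return res;
  } catch (ArenaExhausted &) {
    res.reason = "arena exhausted";
    return res;
  }
}

// [[Rcpp::export(name = ".wfa_align_cpp")]]
List wfa_align_cpp(const std::string &pattern, const std::string &text,
                   int mismatch_x, int gap_open_o, int gap_extend_e,
                   bool adaptive, int min_wf_len, int max_dist, SEXP arena,
                   double arena_bytes) {
  WfaResult r;
  if (arena != R_NilValue) {
    XPtr<Arena> p(arena);
    r = wfa_core(pattern, text, mismatch_x, gap_open_o, gap_extend_e, adaptive,
                 min_wf_len, max_dist, *p);
  } else {
    Arena local((std::size_t)arena_bytes);
    r = wfa_core(pattern, text, mismatch_x, gap_open_o, gap_extend_e, adaptive,
                 min_wf_len, max_dist, local);
  }
  return List::create(_["success"] = r.success,
                      _["score"] = r.success ? wrap(r.score) : R_NilValue,
                      _["cigar"] = r.success ? wrap(r.cigar) : R_NilValue,
                      _["pruned"] = r.pruned,
                      _["reason"] = r.reason);
}
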