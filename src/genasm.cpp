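#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

#include "cigar_util.h"

using namespace Rcpp;

// Bitap / GenASM-style aligner: bit-parallel thresholded edit-distance DP
// with full traceback over the retained status bit-vectors.
//
// Bit convention (stated because the bitap literature uses both): bit b of a
// status vector corresponds to pattern prefix length b+1, i.e. pattern
// position b (0-based); match-is-set. R[j][d] has bit b set iff the edit
// distance between pattern[0..b] and text[0..j-1] is <= d. The virtual
// "empty prefix" bit for prefix length 0 is (j <= d) and enters via the
// shift carry. Words are 64-bit, little-endian word order (word 0 holds
// bits 0..63). A fully consumed pattern is detected at bit m-1 (the
// terminal bit) of R[n][d].

static inline int char_index(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

namespace {

struct BitapRun {
  int m, n, k, w;                  // w = words per vector
  std::vector<uint64_t> masks;     // 4 * w
  std::vector<uint64_t> R;         // (n+1) * (k+1) * w
  uint64_t top_mask;               // valid bits of the last word

  uint64_t *vec(int j, int d) {
    return &R[((std::size_t)j * (k + 1) + d) * w];
  }
  const uint64_t *vec(int j, int d) const {
    return &R[((std::size_t)j * (k + 1) + d) * w];
  }
  // bit for prefix length i (i >= 1); i == 0 handled by caller
  bool bit(int i, int j, int d) const {
    if (d < 0) return false;
    if (i == 0) return j <= d;
    const uint64_t *v = vec(j, d);
    return (v[(i - 1) >> 6] >> ((i - 1) & 63)) & 1u;
  }
};

// dst = (src << 1) | carry, across words, masked to m bits
static void shl1(uint64_t *dst, const uint64_t *src, int w, bool carry,
                 uint64_t top_mask) {
  uint64_t c = carry ? 1u : 0u;
  for (int t = 0; t < w; ++t) {
    uint64_t hi = src[t] >> 63;
    dst[t] = (src[t] << 1) | c;
    c = hi;
  }
  dst[w - 1] &= top_mask;
}

} // namespace

// [[Rcpp::export(name = ".genasm_align_cpp")]]
List genasm_align_cpp(const std::string &pattern, const std::string &text,
                      int k) {
  const int m = (int)pattern.size(), n = (int)text.size();

  if (m == 0) { // empty pattern: n deletions
    bool ok = n <= k;
    return List::create(_["success"] = ok,
                        _["score"] = ok ? wrap(n) : R_NilValue,
                        _["cigar"] = ok ? wrap(n ? std::to_string(n) + "D" : "")
                                        : R_NilValue);
  }

  BitapRun B;
  B.m = m; B.n = n; B.k = k;
  B.w = (m + 63) / 64;
  B.top_mask = (m % 64) ? ((uint64_t(1) << (m % 64)) - 1) : ~uint64_t(0);
  B.masks.assign(4 * (std::size_t)B.w, 0);
  for (int i = 0; i < m; ++i) {
    int c = char_index(pattern[i]);
    if (c < 0) stop("pattern contains a character outside {A,C,G,T}");
    B.masks[(std::size_t)c * B.w + (i >> 6)] |= uint64_t(1) << (i & 63);
  }
  B.R.assign((std::size_t)(n + 1) * (k + 1) * B.w, 0);

  // j = 0 column: distance(prefix i, empty text) = i, so bits 0..d-1 set
  for (int d = 1; d <= k; ++d) {
    uint64_t *v = B.vec(0, d);
    int full = std::min(d, m) >> 6, rem = std::min(d, m) & 63;
    for (int t = 0; t < full; ++t) v[t] = ~uint64_t(0);
    if (rem && full < B.w) v[full] = (uint64_t(1) << rem) - 1;
    v[B.w - 1] &= B.top_mask;
  }

  // four intermediate (scratch) vectors: match, substitution, insertion,
  // deletion contributions to the new status vector
  std::vector<uint64_t> t_match(B.w), t_sub(B.w), t_ins(B.w);

  for (int j = 1; j <= n; ++j) {
    int c = char_index(text[j - 1]);
    if (c < 0) stop("text contains a character outside {A,C,G,T}");
    const uint64_t *pm = &B.masks[(std::size_t)c * B.w];
    for (int d = 0; d <= k; ++d) {
      uint64_t *out = B.vec(j, d);
      shl1(t_match.data(), B.vec(j - 1, d), B.w, (j - 1) <= d, B.top_mask);
      for (int t = 0; t < B.w; ++t) out[t] = t_match[t] & pm[t];
      if (d > 0) {
        shl1(t_sub.data(), B.vec(j - 1, d - 1), B.w, (j - 1) <= (d - 1),
             B.top_mask);
        shl1(t_ins.data(), B.vec(j, d - 1), B.w, j <= (d - 1), B.top_mask);
        const uint64_t *t_del = B.vec(j - 1, d - 1); // unshifted
        for (int t = 0; t < B.w; ++t)
          out[t] |= t_sub[t] | t_ins[t] | t_del[t];
      }
    }
  }

  // score = smallest d whose terminal bit is set
  int score = -1;
  for (int d = 0; d <= k; ++d)
    if (B.bit(m, n, d)) { score = d; break; }
  if (score < 0)
    return List::create(_["success"] = false, _["score"] = R_NilValue,
                        _["cigar"] = R_NilValue);

  // traceback; case priority: match > substitution > deletion > insertion
  std::string ops;
  ops.reserve((std::size_t)m + n);
  int i = m, j = n, d = score;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && pattern[i - 1] == text[j - 1] &&
        B.bit(i - 1, j - 1, d)) {
      ops.push_back('M'); --i; --j;
    } else if (i > 0 && j > 0 && B.bit(i - 1, j - 1, d - 1)) {
      ops.push_back('X'); --i; --j; --d;
    } else if (j > 0 && B.bit(i, j - 1, d - 1)) {
      ops.push_back('D'); --j; --d;
    } else {
      ops.push_back('I'); --i; --d;
    }
  }
  std::reverse(ops.begin(), ops.end());

  return List::create(_["success"] = true, _["score"] = score,
                      _["cigar"] = rle_cigar(ops));
}

// Single-wide-word reference path for m <= 64: same recurrence on plain
// uint64_t scalars, score only. Used to pin the multi-word machinery.
// [[Rcpp::export(name = ".genasm_score_u64_cpp")]]
List genasm_score_u64_cpp(const std::string &pattern, const std::string &text,
                          int k) {
  const int m = (int)pattern.size(), n = (int)text.size();
  if (m > 64) stop("u64 reference path requires m <= 64");
  if (m == 0) {
    bool ok = n <= k;
    return List::create(_["success"] = ok,
                        _["score"] = ok ? wrap(n) : R_NilValue);
  }
  const uint64_t top = (m == 64) ? ~uint64_t(0) : ((uint64_t(1) << m) - 1);
  uint64_t pm[4] = {0, 0, 0, 0};
  for (int i = 0; i < m; ++i) pm[char_index(pattern[i])] |= uint64_t(1) << i;

  std::vector<uint64_t> prev(k + 1), cur(k + 1);
  for (int d = 0; d <= k; ++d)
    prev[d] = (d >= 64) ? top : (((uint64_t(1) << std::min(d, m)) - 1) & top);
  for (int j = 1; j <= n; ++j) {
    const uint64_t cm = pm[char_index(text[j - 1])];
    for (int d = 0; d <= k; ++d) {
      uint64_t match = ((prev[d] << 1) | (((j - 1) <= d) ? 1 : 0)) & cm;
      uint64_t v = match;
      if (d > 0) {
        uint64_t sub = (prev[d - 1] << 1) | (((j - 1) <= (d - 1)) ? 1 : 0);
        uint64_t ins = (cur[d - 1] << 1) | ((j <= (d - 1)) ? 1 : 0);
        v |= sub | ins | prev[d - 1];
      }
      cur[d] = v & top;
    }
    std::swap(prev, cur);
  }
  const uint64_t term = uint64_t(1) << (m - 1);
  for (int d = 0; d <= k; ++d)
    if (prev[d] & term)
      return List::create(_["success"] = true, _["score"] = d);
  return List::create(_["success"] = false, _["score"] = R_NilValue);
}
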