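#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <functional>
#include <string>
#include <vector>

using namespace Rcpp;

// Reference cost oracles: top-down memoized recursion over the alignment
// cost recurrences. Deliberately a different route from the aligners'
// bottom-up table fill + traceback, so the two can check each other.

static const int32_t ORA_INF = INT32_MAX / 4;

// [[Rcpp::export(name = ".nw_cost_ref_cpp")]]
int nw_cost_ref_cpp(const std::string &p, const std::string &t, int match_a,
                    int mismatch_x, int indel_e) {
  const int m = (int)p.size(), n = (int)t.size();
  std::vector<int32_t> memo(((std::size_t)m + 1) * (n + 1), -1);
  std::function<int32_t(int, int)> f = [&](int i, int j) -> int32_t {
    int32_t &slot = memo[(std::size_t)i * (n + 1) + j];
    if (slot >= 0) return slot;
    int32_t v;
    if (i == 0) v = (int32_t)j * indel_e;
    else if (j == 0) v = (int32_t)i * indel_e;
    else {
      v = f(i - 1, j - 1) + (p[i - 1] == t[j - 1] ? match_a : mismatch_x);
      v = std::min(v, f(i - 1, j) + indel_e);
      v = std::min(v, f(i, j - 1) + indel_e);
    }
    return slot = v;
  };
  return f(m, n);
}

// Three mutually recursive memoized states for the affine (Gotoh) cost.
// [[Rcpp::export(name = ".swg_cost_ref_cpp")]]
int swg_cost_ref_cpp(const std::string &p, const std::string &t, int match_a,
                     int mismatch_x, int gap_open_o, int gap_extend_e) {
  const int m = (int)p.size(), n = (int)t.size();
  const std::size_t sz = ((std::size_t)m + 1) * (n + 1);
  std::vector<int32_t> memo(3 * sz, -1); // state-major: H, I, D
  const int32_t oe = gap_open_o + gap_extend_e;

  std::function<int32_t(int, int, int)> f = [&](int st, int i,
                                                int j) -> int32_t {
    int32_t &slot = memo[(std::size_t)st * sz + (std::size_t)i * (n + 1) + j];
    if (slot >= 0) return slot;
    int32_t v;
    if (st == 1) { // gap consuming pattern
      if (i == 0) v = ORA_INF;
      else if (j == 0) v = gap_open_o + (int32_t)i * gap_extend_e;
      else v = std::min(f(0, i - 1, j) + oe, f(1, i - 1, j) + gap_extend_e);
    } else if (st == 2) { // gap consuming text
      if (j == 0) v = ORA_INF;
      else if (i == 0) v = gap_open_o + (int32_t)j * gap_extend_e;
      else v = std::min(f(0, i, j - 1) + oe, f(2, i, j - 1) + gap_extend_e);
    } else {
      if (i == 0 && j == 0) v = 0;
      else if (i == 0) v = f(2, i, j);
      else if (j == 0) v = f(1, i, j);
      else {
        v = f(0, i - 1, j - 1) + (p[i - 1] == t[j - 1] ? match_a : mismatch_x);
        v = std::min(v, std::min(f(1, i, j), f(2, i, j)));
      }
    }
    v = std::min(v, ORA_INF);
    return slot = v;
  };
  return f(0, m, n);
}
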