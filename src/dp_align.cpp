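#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

#include "cigar_util.h"

using namespace Rcpp;

// Costs are minimized; cells are kept in int32 internally. The modelled
// device stores int16 cells: every cost reachable under the supported
// lengths and default penalties fits 16 bits well before the capacity
// ceilings bite, and widening internally cannot change any reachable value.
static const int32_t DP_INF = INT32_MAX / 4;

// ---------------------------------------------------------------------------
// Needleman-Wunsch, linear gap model, full table + traceback.
// Tie-break: diagonal (M/X) > D (consume text) > I (consume pattern).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(const std::string &pattern, const std::string &text,
                  int match_a, int mismatch_x, int indel_e) {
  const int m = (int)pattern.size(), n = (int)text.size();
  const std::size_t ncol = (std::size_t)n + 1;
  std::vector<int32_t> H(((std::size_t)m + 1) * ncol);

  for (int j = 0; j <= n; ++j) H[j] = (int32_t)j * indel_e;
  for (int i = 1; i <= m; ++i) {
    int32_t *row = &H[(std::size_t)i * ncol];
    const int32_t *prev = &H[(std::size_t)(i - 1) * ncol];
    row[0] = (int32_t)i * indel_e;
    const char pc = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      int32_t diag = prev[j - 1] + (pc == text[j - 1] ? match_a : mismatch_x);
      int32_t del = row[j - 1] + indel_e;   // consume text
      int32_t ins = prev[j] + indel_e;      // consume pattern
      row[j] = std::min(diag, std::min(del, ins));
    }
  }

  // traceback
  std::string ops;
  ops.reserve((std::size_t)m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    const int32_t cur = H[(std::size_t)i * ncol + j];
    if (i > 0 && j > 0) {
      const bool eq = pattern[i - 1] == text[j - 1];
      const int32_t diag =
          H[(std::size_t)(i - 1) * ncol + (j - 1)] + (eq ? match_a : mismatch_x);
      if (cur == diag) {
        ops.push_back(eq ? 'M' : 'X');
        --i; --j;
        continue;
      }
    }
    if (j > 0 && cur == H[(std::size_t)i * ncol + (j - 1)] + indel_e) {
      ops.push_back('D');
      --j;
      continue;
    }
    ops.push_back('I');
    --i;
  }
  std::reverse(ops.begin(), ops.end());

  return List::create(_["score"] = H[(std::size_t)m * ncol + n],
                      _["cigar"] = rle_cigar(ops));
}

// ---------------------------------------------------------------------------
// Smith-Waterman-Gotoh, affine gap model (gap of length g costs o + g*e),
// three logical tables H (overall/match), I (gap in text, consumes pattern),
// D (gap in pattern, consumes text).
//
// Physical storage is selectable: "interleaved" keeps one record of three
// cells per (i,j) so a row fetch touches all three states contiguously (the
// layout used for single-DMA row transfers on the modelled device);
// "separate" keeps three plain tables. Both must be bit-identical.
// ---------------------------------------------------------------------------

struct SwgTables {
  std::size_t ncol;
  bool interleaved;
  std::size_t plane; // cells per table when separate
  std::vector<int32_t> buf;
  SwgTables(int m, int n, bool inter)
      : ncol((std::size_t)n + 1), interleaved(inter),
        plane(((std::size_t)m + 1) * ((std::size_t)n + 1)),
        buf(3 * ((std::size_t)m + 1) * ((std::size_t)n + 1)) {}
  int32_t &at(int state, int i, int j) { // state: 0=H,1=I,2=D
    std::size_t cell = (std::size_t)i * ncol + j;
    return interleaved ? buf[3 * cell + state] : buf[(std::size_t)state * plane + cell];
  }
};

// [[Rcpp::export(name = ".swg_align_cpp")]]
List swg_align_cpp(const std::string &pattern, const std::string &text,
                   int match_a, int mismatch_x, int gap_open_o,
                   int gap_extend_e, bool interleaved) {
  const int m = (int)pattern.size(), n = (int)text.size();
  SwgTables T(m, n, interleaved);
  const int32_t oe = gap_open_o + gap_extend_e;

  T.at(0, 0, 0) = 0;
  T.at(1, 0, 0) = DP_INF;
  T.at(2, 0, 0) = DP_INF;
  for (int i = 1; i <= m; ++i) {
    T.at(1, i, 0) = gap_open_o + (int32_t)i * gap_extend_e;
    T.at(0, i, 0) = T.at(1, i, 0);
    T.at(2, i, 0) = DP_INF;
  }
  for (int j = 1; j <= n; ++j) {
    T.at(2, 0, j) = gap_open_o + (int32_t)j * gap_extend_e;
    T.at(0, 0, j) = T.at(2, 0, j);
    T.at(1, 0, j) = DP_INF;
  }
  for (int i = 1; i <= m; ++i) {
    const char pc = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      int32_t ins = std::min(T.at(0, i - 1, j) + oe, T.at(1, i - 1, j) + gap_extend_e);
      int32_t del = std::min(T.at(0, i, j - 1) + oe, T.at(2, i, j - 1) + gap_extend_e);
      int32_t diag =
          T.at(0, i - 1, j - 1) + (pc == text[j - 1] ? match_a : mismatch_x);
      T.at(1, i, j) = ins;
      T.at(2, i, j) = del;
      T.at(0, i, j) = std::min(diag, std::min(ins, del));
    }
  }

  // three-state traceback; prefer diagonal > D > I when leaving H, and
  // staying in a gap state (extension) over re-opening.
  std::string ops;
  ops.reserve((std::size_t)m + n);
  int i = m, j = n, state = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i > 0 && j > 0) {
        const bool eq = pattern[i - 1] == text[j - 1];
        const int32_t diag =
            T.at(0, i - 1, j - 1) + (eq ? match_a : mismatch_x);
        if (T.at(0, i, j) == diag) {
          ops.push_back(eq ? 'M' : 'X');
          --i; --j;
          continue;
        }
      }
      if (j > 0 && T.at(0, i, j) == T.at(2, i, j)) { state = 2; continue; }
      state = 1;
    } else if (state == 2) { // deletion run (consumes text)
      ops.push_back('D');
      const int32_t cur = T.at(2, i, j);
      --j;
      if (j > 0 && cur == T.at(2, i, j) + gap_extend_e) state = 2;
      else if (cur == T.at(0, i, j) + oe) state = 0;
      // else: boundary column, remain in D
    } else { // insertion run (consumes pattern)
      ops.push_back('I');
      const int32_t cur = T.at(1, i, j);
      --i;
      if (i > 0 && cur == T.at(1, i, j) + gap_extend_e) state = 1;
      else if (cur == T.at(0, i, j) + oe) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());

  return List::create(_["score"] = T.at(0, m, n), _["cigar"] = rle_cigar(ops));
}
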