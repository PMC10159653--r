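#ifndef PIMALIGN_CIGAR_UTIL_H
#define PIMALIGN_CIGAR_UTIL_H

#include <string>
#include <cstdint>

// Run-length encode a forward sequence of op characters (M/X/I/D)
// into SAM-style extended CIGAR text, e.g. "23M1X76M".
inline std::string rle_cigar(const std::string &ops) {
  std::string out;
  std::size_t i = 0;
  while (i < ops.size()) {
    std::size_t j = i;
    while (j < ops.size() && ops[j] == ops[i]) ++j;
    out += std::to_string(j - i);
    out.push_back(ops[i]);
    i = j;
  }
  return out;
}

#endif
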