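// Adapter search used by trim_adapter(): left-most occurrence of the adapter
// (full or read-terminal suffix overlap) with a bounded mismatch count.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".trim_adapter_cpp")]]
CharacterVector trim_adapter_cpp(CharacterVector reads, std::string adapter,
                                 int min_overlap, int max_mismatch) {
  int nr = reads.size();
  int alen = adapter.size();
  CharacterVector out(nr);
  for (int r = 0; r < nr; ++r) {
    if (reads[r] == NA_STRING) { out[r] = NA_STRING; continue; }
    std::string rd = as<std::string>(reads[r]);
    int rl = rd.size();
    bool found = false;
    for (int p = 0; p < rl; ++p) {
      int complen = std::min(alen, rl - p);
      if (complen < min_overlap) break;   // only shorter overlaps remain
      int mm = 0;
      bool ok = true;
      for (int k = 0; k < complen; ++k) {
        if (rd[p + k] != adapter[k]) {
          if (++mm > max_mismatch) { ok = false; break; }
        }
      }
      if (ok) {
        out[r] = rd.substr(0, p);
        found = true;
        break;
      }
    }
    if (!found) out[r] = NA_STRING;
  }
  return out;
}
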