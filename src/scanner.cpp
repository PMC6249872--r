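#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Complete ungapped scan of an encoded subject (base codes 1..4, sentinels
// and N as 0) for full-length placements of an encoded pattern with at
// least `id_min` identities (i.e. at most L - id_min mismatches).
//
// Wu-Manber bit-parallel approximate matching under the substitution-only
// (Hamming) model: R[d] tracks, per text position, the set of pattern
// prefixes matching with at most d mismatches. A placement is reported
// when the full-length bit of R[budget] is set; the exact identity count
// is then recomputed directly (reported placements are sparse).
// [[Rcpp::export(name = ".scan_identities")]]
List scan_identities(IntegerVector subject, IntegerVector pattern,
                     int id_min) {
  const int n = subject.size();
  const int L = pattern.size();
  std::vector<int> starts;
  std::vector<int> idents;
  if (L == 0 || L > 63 || n < L || id_min > L) {
    return List::create(_["start"] = IntegerVector(0),
                        _["identities"] = IntegerVector(0));
  }
  const int budget = L - id_min;  // mismatches allowed
  const int *s = INTEGER(subject);
  const int *p = INTEGER(pattern);

  uint64_t B[5] = {0, 0, 0, 0, 0};  // per-base prefix masks; code 0 unset
  for (int i = 0; i < L; ++i) {
    if (p[i] >= 1 && p[i] <= 4) B[p[i]] |= (uint64_t(1) << i);
  }
  const uint64_t full = uint64_t(1) << (L - 1);

  uint64_t R[64] = {0};  // budget <= L - 1 < 63
  for (int pos = 0; pos < n; ++pos) {
    const int c = s[pos];
    const uint64_t Bc = (c >= 1 && c <= 4) ? B[c] : 0;
    uint64_t prev = R[0];  // previous step's R[d-1], carried in place
    R[0] = ((prev << 1) | 1) & Bc;
    for (int d = 1; d <= budget; ++d) {
      const uint64_t cur = R[d];
      R[d] = (((cur << 1) | 1) & Bc) | ((prev << 1) | 1);
      prev = cur;
    }
    if (R[budget] & full) {
      const int off = pos - L + 1;
      int ident = 0;
      for (int j = 0; j < L; ++j) {
        if (s[off + j] == p[j]) ++ident;
      }
      if (ident >= id_min) {  // guard; equivalent by construction
        starts.push_back(off + 1);  // 1-based
        idents.push_back(ident);
      }
    }
  }
  return List::create(_["start"] = wrap(starts),
                      _["identities"] = wrap(idents));
}
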