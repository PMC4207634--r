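#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; -1 for anything else.
static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Exact k-mer multiplicity histogram over a set of reads.
// Rolling 2-bit encoding; k-mers spanning a non-ACGT base are skipped.
// With canonical = true a k-mer is pooled with its reverse complement
// (the lexicographically smaller encoding is counted).
// [[Rcpp::export]]
List kmer_histogram_cpp(CharacterVector reads, int k, bool canonical) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, uint32_t> tab;
  tab.reserve(1 << 23);  // avoid rehashing at typical desk-scale inputs
  tab.max_load_factor(0.7f);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift_rc = 2 * (k - 1);
  double total = 0.0;

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int len = LENGTH(STRING_ELT(reads, r));
    uint64_t fwd = 0, rc = 0;
    int filled = 0;
    for (int i = 0; i < len; ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { filled = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << shift_rc);
      if (++filled >= k) {
        uint64_t key = canonical ? std::min(fwd, rc) : fwd;
        ++tab[key];
        total += 1.0;
      }
    }
  }

  // histogram of multiplicities (count of distinct k-mers seen m times)
  std::map<uint32_t, double> hist;
  for (const auto &kv : tab) hist[kv.second] += 1.0;

  IntegerVector mult(hist.size());
  NumericVector cnt(hist.size());
  R_xlen_t i = 0;
  for (const auto &kv : hist) { mult[i] = (int)kv.first; cnt[i] = kv.second; ++i; }
  return List::create(_["multiplicity"] = mult, _["count"] = cnt,
                      _["total_kmers"] = total,
                      _["distinct_kmers"] = (double)tab.size());
}
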