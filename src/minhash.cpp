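// Bottom-s MinHash sketching of canonical nucleotide k-mers.
//
// k-mers are 2-bit packed (A=0, C=1, G=2, T=3; anything else breaks the
// window), canonicalised as min(kmer, reverse complement), hashed with
// splitmix64 and masked to 53 bits so every hash is exactly representable
// as an R double.

#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export(name = ".sketch_kmers")]]
List sketch_kmers(CharacterVector seqs, int k, int s) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  if (s < 1) stop("sketch size must be >= 1");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const uint64_t hmask = (1ULL << 53) - 1;
  std::unordered_set<uint64_t> hashes;
  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    const char *str = CHAR(STRING_ELT(seqs, si));
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (const char *p = str; *p; ++p) {
      int code;
      switch (*p) {
        case 'A': case 'a': code = 0; break;
        case 'C': case 'c': code = 1; break;
        case 'G': case 'g': code = 2; break;
        case 'T': case 't': code = 3; break;
        default: code = -1;
      }
      if (code < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)code) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - code) << (2 * (k - 1)));
      if (++valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        hashes.insert(splitmix64(canon) & hmask);
      }
    }
  }
  std::vector<double> v(hashes.begin(), hashes.end());
  std::sort(v.begin(), v.end());
  size_t keep = std::min<size_t>((size_t)s, v.size());
  return List::create(_["hashes"] = NumericVector(v.begin(), v.begin() + keep),
                      _["distinct_kmers"] = (double)v.size());
}
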