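#include <Rcpp.h>
#include <cstdint>

// Deterministic, seed-mixed mapping of read names to [0, 1). A keep/drop
// decision per read name must be identical wherever the name recurs in
// the stream (mates, secondary and supplementary records), so it is a
// pure function of (seed, name) rather than a draw from a streaming RNG.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export]]
Rcpp::NumericVector hash_unit(Rcpp::CharacterVector names, double seed) {
  const uint64_t seed_mix = splitmix64((uint64_t)(int64_t)seed);
  const double inv = 1.0 / 9007199254740992.0; /* 2^-53 */
  Rcpp::NumericVector out(names.size());
  for (R_xlen_t i = 0; i < names.size(); ++i) {
    const char *s = CHAR(STRING_ELT(names, i));
    uint64_t h = 0xCBF29CE484222325ULL ^ seed_mix; /* FNV-1a basis */
    for (; *s; ++s) {
      h ^= (uint64_t)(unsigned char)*s;
      h *= 0x100000001B3ULL;
    }
    out[i] = (double)(splitmix64(h) >> 11) * inv;
  }
  return out;
}
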