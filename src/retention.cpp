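#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
using namespace Rcpp;

// Seeded, order-independent per-read retention.
//
// Each read name is reduced to a 64-bit FNV-1a hash, mixed with the seed
// through a splitmix64 finalizer, and mapped to [0, 1); the read is retained
// when that value falls below the normalization factor. The decision depends
// only on (name, seed), so it is stable under re-ordering, re-runs and
// pair lookups (mates share a name), mirroring the samtools -s contract
// (fraction + seed, name-hash based) without promising its exact bytes.

static inline uint64_t fnv1a64(const char *s) {
  uint64_t h = 1469598103934665603ULL;
  for (; *s; ++s) {
    h ^= (uint64_t)(unsigned char)(*s);
    h *= 1099511628211ULL;
  }
  return h;
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double unit_value(const char *name, uint64_t seed) {
  uint64_t h = splitmix64(fnv1a64(name) ^ splitmix64(seed));
  // 53-bit mantissa -> uniform double in [0, 1)
  return (double)(h >> 11) * (1.0 / 9007199254740992.0);
}

//' @noRd
// [[Rcpp::export(name = ".retain_by_name")]]
LogicalVector retain_by_name(CharacterVector names, double nf, double seed) {
  const R_xlen_t n = names.size();
  LogicalVector keep(n);
  const uint64_t s = (uint64_t)seed;
  for (R_xlen_t i = 0; i < n; ++i) {
    keep[i] = unit_value(CHAR(STRING_ELT(names, i)), s) < nf;
  }
  return keep;
}

// Applies the identical retention rule to n synthetic read names
// ("r1" ... "rn") without materializing them in R; used to exercise the
// downsampler at full experimental scale (tens of millions of reads).
//' @noRd
// [[Rcpp::export(name = ".retained_count_synthetic")]]
double retained_count_synthetic(double n, double nf, double seed) {
  const uint64_t s = (uint64_t)seed;
  const int64_t nn = (int64_t)n;
  int64_t kept = 0;
  char buf[32];
  for (int64_t i = 1; i <= nn; ++i) {
    snprintf(buf, sizeof(buf), "r%lld", (long long)i);
    if (unit_value(buf, s) < nf) ++kept;
  }
  return (double)kept;
}
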