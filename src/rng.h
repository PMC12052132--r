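#ifndef MORANCOLONIZE_RNG_H
#define MORANCOLONIZE_RNG_H

#include <cstdint>
#include <cmath>
#include <random>

namespace morancolonize {

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// One independent substream per replicate: root seed and stream id are mixed
// through splitmix64 before seeding the generator, so replicate i is
// reproducible in isolation from (seed, i) alone.
class SubstreamRNG {
public:
  SubstreamRNG(uint64_t root, uint64_t stream) {
    uint64_t s = splitmix64(splitmix64(root) ^
                            (0xD2B74407B1CE6E93ULL * (stream + 1)));
    gen_.seed(s);
    gen_.discard(8);
  }

  uint64_t next() { return gen_(); }

  // Unbiased integer in [0, s); multiply-shift with rejection. Hand-rolled
  // because std::uniform_int_distribution output is not portable across
  // standard-library implementations.
  uint64_t below(uint64_t s) {
    uint64_t x = gen_();
    __uint128_t m = (__uint128_t)x * (__uint128_t)s;
    uint64_t l = (uint64_t)m;
    if (l < s) {
      uint64_t t = (0 - s) % s;
      while (l < t) {
        x = gen_();
        m = (__uint128_t)x * (__uint128_t)s;
        l = (uint64_t)m;
      }
    }
    return (uint64_t)(m >> 64);
  }

  // Uniform on (0, 1]; strictly positive so log() is always finite.
  double unif_pos() { return (double)((gen_() >> 11) + 1) * 0x1.0p-53; }

  double exp_mean(double mean) { return -std::log(unif_pos()) * mean; }

private:
  std::mt19937_64 gen_;
};

}  // namespace morancolonize

#endif
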