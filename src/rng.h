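#pragma once
#include <cstdint>

// Small deterministic PRNG (xorshift128+ seeded via splitmix64), independent of
// R's RNG so that realization r of an ensemble can use substream (base, r) and
// parallel/serial execution order cannot change results.
struct StreamRng {
  uint64_t s0, s1;

  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  explicit StreamRng(uint64_t seed) {
    uint64_t x = seed;
    s0 = splitmix(x);
    s1 = splitmix(x);
    if (s0 == 0 && s1 == 0) s1 = 0x9E3779B97F4A7C15ULL;
  }

  uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }

  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }

  // uniform integer in {0, ..., n-1}, n small
  int randint(int n) {
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

// substream seed for realization/restart r under base seed
inline uint64_t substream_seed(uint64_t base, uint64_t r) {
  uint64_t x = base;
  uint64_t h = StreamRng::splitmix(x);
  x = h ^ (r * 0xBF58476D1CE4E5B9ULL);
  return StreamRng::splitmix(x);
}
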