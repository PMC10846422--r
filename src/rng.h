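#pragma once
#include <cstdint>
#include <cmath>

// xoshiro256** with splitmix64 seeding. One independently-seeded stream per
// photon packet (stream id mixed into the seed), so transport results are
// reproducible and independent of packet execution order.
struct Rng {
  uint64_t s[4];

  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static Rng stream(uint64_t seed, uint64_t id) {
    return Rng(seed ^ (0x9e3779b97f4a7c15ULL * (id + 1)));
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0,1), never exactly 0 or 1
  double runif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Exponential free path for total attenuation mu_t (cm^-1); mean 1/mu_t.
inline double sample_path(double mu_t, Rng& rng) {
  return -std::log(rng.runif()) / mu_t;
}

// Henyey-Greenstein deflection cosine for anisotropy g in (-1, 1).
inline double sample_hg_cos(double g, Rng& rng) {
  const double u = rng.runif();
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  const double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}
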