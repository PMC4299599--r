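#ifndef FCCSTOOLS_RNG_H
#define FCCSTOOLS_RNG_H

#include <cstdint>
#include <cmath>
#include <cstdlib>

// Self-contained RNG stack for the Brownian-dynamics simulator.
// xoshiro256++ streams seeded via splitmix64 so that every particle owns an
// independent, order-invariant substream derived from the user-facing seed.

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix(uint64_t& x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 0x9E3779B97F4A7C15ULL;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform in (0, 1] (safe for log())
  inline double unif_pos() { return ((next() >> 11) + 1.0) * 0x1.0p-53; }
  inline uint32_t next32() { return (uint32_t)(next() >> 32); }
};

// Derive a substream seed: mixes the root seed with a stream tag.
inline uint64_t mix_seed(uint64_t root, uint64_t tag) {
  uint64_t x = root * 0x9E3779B97F4A7C15ULL + tag;
  x = Xoshiro::splitmix(x);
  return x;
}

// --- Ziggurat normal sampler (Marsaglia & Tsang, 128 layers) ---------------

struct Ziggurat {
  uint32_t kn[128];
  double wn[128], fn[128];

  Ziggurat() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }

  inline double draw(Xoshiro& rng) const {
    for (;;) {
      int32_t hz = (int32_t)rng.next32();
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t ahz = (hz < 0) ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (ahz < kn[iz]) return hz * wn[iz];
      // tail / wedge handling
      const double r = 3.442619855899;
      double x = hz * wn[iz];
      if (iz == 0) {
        double y;
        do {
          x = -std::log(rng.unif_pos()) * 0.2904764;  // 1/r
          y = -std::log(rng.unif_pos());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -r - x;
      }
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
      // else resample from scratch
    }
  }
};

inline const Ziggurat& ziggurat() {
  static const Ziggurat z;
  return z;
}

// --- Poisson (exact; Knuth with additive chunking for large means) ---------

inline int rpois_knuth(Xoshiro& rng, double mu) {
  double L = std::exp(-mu), p = 1.0;
  int k = 0;
  do {
    ++k;
    p *= rng.unif_pos();
  } while (p > L);
  return k - 1;
}

inline int rpois(Xoshiro& rng, double mu) {
  if (mu <= 0.0) return 0;
  int k = 0;
  while (mu > 30.0) {  // Poisson(a + b) = Poisson(a) + Poisson(b)
    k += rpois_knuth(rng, 30.0);
    mu -= 30.0;
  }
  return k + rpois_knuth(rng, mu);
}

// --- Binomial (small n; Bernoulli loop) -------------------------------------

inline int rbinom_small(Xoshiro& rng, int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  if (n == 1) return rng.unif() < p ? 1 : 0;
  int k = 0;
  for (int i = 0; i < n; ++i)
    if (rng.unif() < p) ++k;
  return k;
}

// --- Fast table-based exp(-u) for u in [0, UMAX], else 0 --------------------
// Linear interpolation; absolute error < 1e-6, relative error < 2e-6 over the
// retained range. Used only inside the Gaussian detection profile.

struct NegExpTable {
  static const int N = 8192;
  double umax, inv_h;
  double tab[N + 2];
  explicit NegExpTable(double umax_) : umax(umax_) {
    inv_h = N / umax;
    for (int i = 0; i <= N + 1; ++i) tab[i] = std::exp(-i * umax / N);
  }
  inline double operator()(double u) const {
    if (u >= umax) return 0.0;
    double t = u * inv_h;
    int i = (int)t;
    double f = t - i;
    return tab[i] + f * (tab[i + 1] - tab[i]);
  }
};

#endif
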