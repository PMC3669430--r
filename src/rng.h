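#ifndef MMCG_RNG_H
#define MMCG_RNG_H

#include <cstdint>
#include <cmath>

// Counter-seeded xoshiro256++ with a splitmix64 seeding chain.
// Each integration step draws from its own stream (seed, stream_id), so a
// trajectory is bit-reproducible and single steps compose exactly into runs.
namespace mmcg {

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

class RNG {
public:
  RNG(uint64_t seed, uint64_t stream) : has_spare_(false), spare_(0.0) {
    uint64_t sm = seed ^ (stream * 0xD1342543DE82EF95ULL + 0x2545F4914F6CDD1DULL);
    for (int i = 0; i < 4; ++i) s_[i] = splitmix64(sm);
    // avoid the all-zero state (astronomically unlikely, still guarded)
    if ((s_[0] | s_[1] | s_[2] | s_[3]) == 0) s_[0] = 1;
  }

  uint64_t next_u64() {
    const uint64_t result = rotl(s_[0] + s_[3], 23) + s_[0];
    const uint64_t t = s_[1] << 17;
    s_[2] ^= s_[0];
    s_[3] ^= s_[1];
    s_[1] ^= s_[2];
    s_[0] ^= s_[3];
    s_[2] ^= t;
    s_[3] = rotl(s_[3], 45);
    return result;
  }

  // uniform in [0, 1)
  double uniform() {
    return (next_u64() >> 11) * 0x1.0p-53;
  }

  // standard normal via the polar (Marsaglia) method; deterministic for a
  // given stream because rejection consumes draws in a fixed order
  double gaussian() {
    if (has_spare_) {
      has_spare_ = false;
      return spare_;
    }
    double u, v, s;
    do {
      u = 2.0 * uniform() - 1.0;
      v = 2.0 * uniform() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    const double m = std::sqrt(-2.0 * std::log(s) / s);
    spare_ = v * m;
    has_spare_ = true;
    return u * m;
  }

private:
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t s_[4];
  bool has_spare_;
  double spare_;
};

} // namespace mmcg

#endif
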