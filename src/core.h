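#ifndef STROBEMAP_CORE_H
#define STROBEMAP_CORE_H

#include <cstdint>
#include <string>
#include <vector>
#include <stdexcept>

// 2-bit nucleotide codes: A=00, C=01, G=10, T=11; first base of a k-mer
// occupies the most significant 2 bits of its integer encoding.
inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// Fixed xorshift-multiply 64-bit mixing permutation (splitmix64 finalizer
// constants). Bijective over the 64-bit space; the inverse below is used as
// an independent oracle for that property.
inline uint64_t mix64(uint64_t x) {
    x ^= x >> 30;
    x *= 0xbf58476d1ce4e5b9ULL;
    x ^= x >> 27;
    x *= 0x94d049bb133111ebULL;
    x ^= x >> 31;
    return x;
}

// modular inverse of an odd 64-bit multiplier (Newton iteration)
inline uint64_t inv_mult64(uint64_t a) {
    uint64_t x = a;
    for (int i = 0; i < 6; ++i) x *= 2 - a * x;
    return x;
}

// invert y = x ^ (x >> r)
inline uint64_t unxorshift(uint64_t y, int r) {
    uint64_t x = y;
    for (int i = 0; i < 8; ++i) x = y ^ (x >> r);
    return x;
}

inline uint64_t unmix64(uint64_t x) {
    x = unxorshift(x, 31);
    x *= inv_mult64(0x94d049bb133111ebULL);
    x = unxorshift(x, 27);
    x *= inv_mult64(0xbf58476d1ce4e5b9ULL);
    x = unxorshift(x, 30);
    return x;
}

// reverse complement of a 2-bit packed k-mer held in the low 2k bits
inline uint64_t revcomp_code(uint64_t x, int k) {
    x = ~x;
    x = ((x & 0x3333333333333333ULL) << 2) | ((x >> 2) & 0x3333333333333333ULL);
    x = ((x & 0x0F0F0F0F0F0F0F0FULL) << 4) | ((x >> 4) & 0x0F0F0F0F0F0F0F0FULL);
    x = ((x & 0x00FF00FF00FF00FFULL) << 8) | ((x >> 8) & 0x00FF00FF00FF00FFULL);
    x = ((x & 0x0000FFFF0000FFFFULL) << 16) | ((x >> 16) & 0x0000FFFF0000FFFFULL);
    x = (x << 32) | (x >> 32);
    return x >> (64 - 2 * k);
}

// canonical hash of a k-mer given forward and reverse-complement codes:
// hash of the numerically (= lexicographically, under 2-bit codes) smaller
inline uint64_t canonical_hash(uint64_t fwd, uint64_t rc) {
    return mix64(fwd < rc ? fwd : rc);
}

// number of set bits among the p leftmost bits
inline int popcount_top(uint64_t x, int p) {
    if (p <= 0) return 0;
    uint64_t mask = (p >= 64) ? ~0ULL : (~0ULL << (64 - p));
    return __builtin_popcountll(x & mask);
}

inline uint64_t top_mask(int p) {
    return (p >= 64) ? ~0ULL : (p <= 0 ? 0ULL : (~0ULL << (64 - p)));
}

std::string hash_to_hex(uint64_t x);
uint64_t hex_to_hash(const std::string &s);

struct SyncmerVec {
    std::vector<int64_t> pos;      // 0-based start
    std::vector<uint64_t> hash;    // canonical k-mer hash
};

// canonical open syncmers of seq (k, s, t with t 1-based in [1, k-s+1])
SyncmerVec open_syncmers_core(const std::string &seq, int k, int s, int t);

struct SeedVec {
    std::vector<uint64_t> hash;    // symmetric strobemer hash h'
    std::vector<int64_t> q_s;      // start of first strobe
    std::vector<int64_t> q_e;      // end (exclusive) of second strobe
    std::vector<int> offset;       // second-strobe start - first-strobe start
    std::vector<int> orient;       // 0 fwd, 1 rc (reads only)
    std::vector<int> is_single;    // 1 = single-syncmer fallback
};

SeedVec link_seeds_core(const SyncmerVec &sync, int wmin, int wmax, int p,
                        int k, int max_seed_len, bool reverse_iter,
                        int64_t seq_len);

#endif
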