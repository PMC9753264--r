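#include <Rcpp.h>
#include <cstdio>
#include <cinttypes>
#include "core.h"

using namespace Rcpp;

std::string hash_to_hex(uint64_t x) {
    char buf[17];
    std::snprintf(buf, sizeof(buf), "%016" PRIx64, x);
    return std::string(buf);
}

uint64_t hex_to_hash(const std::string &s) {
    if (s.empty() || s.size() > 16)
        throw std::invalid_argument("hash must be 1-16 hex digits");
    uint64_t x = 0;
    for (char c : s) {
        int v;
        if (c >= '0' && c <= '9') v = c - '0';
        else if (c >= 'a' && c <= 'f') v = c - 'a' + 10;
        else if (c >= 'A' && c <= 'F') v = c - 'A' + 10;
        else throw std::invalid_argument("invalid hex digit in hash");
        x = (x << 4) | (uint64_t)v;
    }
    return x;
}

// [[Rcpp::export]]
double cpp_encode_kmer(std::string seq, int start0, int k) {
    if (k < 1 || k > 26)
        stop("k must be in [1, 26] for exact integer return");
    if (start0 < 0 || (size_t)(start0 + k) > seq.size())
        stop("k-mer window out of range");
    uint64_t x = 0;
    for (int i = 0; i < k; ++i) {
        int c = base_code(seq[start0 + i]);
        if (c < 0) stop("undecodable k-mer: ambiguous base in window");
        x = (x << 2) | (uint64_t)c;
    }
    return (double)x;
}

// [[Rcpp::export]]
std::string cpp_decode_kmer(double code, int k) {
    if (k < 1 || k > 26) stop("k must be in [1, 26]");
    uint64_t x = (uint64_t)code;
    std::string out(k, 'A');
    const char *bases = "ACGT";
    for (int i = k - 1; i >= 0; --i) {
        out[i] = bases[x & 3];
        x >>= 2;
    }
    return out;
}

static char iupac_complement(char c) {
    switch (c) {
    case 'A': return 'T'; case 'a': return 't';
    case 'C': return 'G'; case 'c': return 'g';
    case 'G': return 'C'; case 'g': return 'c';
    case 'T': return 'A'; case 't': return 'a';
    case 'U': return 'A'; case 'u': return 'a';
    case 'N': return 'N'; case 'n': return 'n';
    case 'R': return 'Y'; case 'Y': return 'R';
    case 'S': return 'S'; case 'W': return 'W';
    case 'K': return 'M'; case 'M': return 'K';
    case 'B': return 'V'; case 'V': return 'B';
    case 'D': return 'H'; case 'H': return 'D';
    case 'r': return 'y'; case 'y': return 'r';
    case 's': return 's'; case 'w': return 'w';
    case 'k': return 'm'; case 'm': return 'k';
    case 'b': return 'v'; case 'v': return 'b';
    case 'd': return 'h'; case 'h': return 'd';
    default: return 0;
    }
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string seq) {
    std::string out(seq.size(), 'N');
    size_t n = seq.size();
    for (size_t i = 0; i < n; ++i) {
        char c = iupac_complement(seq[n - 1 - i]);
        if (c == 0) stop("non-IUPAC character in sequence");
        out[i] = c;
    }
    return out;
}

// [[Rcpp::export]]
std::string cpp_hash64_hex(std::string hex) {
    return hash_to_hex(mix64(hex_to_hash(hex)));
}

// [[Rcpp::export]]
std::string cpp_unhash64_hex(std::string hex) {
    return hash_to_hex(unmix64(hex_to_hash(hex)));
}

// [[Rcpp::export]]
CharacterVector cpp_hash64_hex_vec(CharacterVector hex) {
    CharacterVector out(hex.size());
    for (R_xlen_t i = 0; i < hex.size(); ++i)
        out[i] = hash_to_hex(mix64(hex_to_hash(as<std::string>(hex[i]))));
    return out;
}

SyncmerVec open_syncmers_core(const std::string &seq, int k, int s, int t) {
    SyncmerVec out;
    int64_t n = (int64_t)seq.size();
    if (n < k) return out;
    int win = k - s + 1;
    // canonical s-mer hashes and k-mer hashes at every decodable start
    std::vector<uint64_t> shash(n - s + 1);
    std::vector<char> kvalid(n - k + 1, 0);
    std::vector<uint64_t> khash(n - k + 1);
    uint64_t sfwd = 0, src = 0, kfwd = 0, krc = 0;
    uint64_t smask = (s < 32) ? ((1ULL << (2 * s)) - 1) : ~0ULL;
    uint64_t kmask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int64_t run = 0;
    for (int64_t i = 0; i < n; ++i) {
        int c = base_code(seq[i]);
        if (c < 0) { run = 0; continue; }
        sfwd = ((sfwd << 2) | (uint64_t)c) & smask;
        src = (src >> 2) | ((uint64_t)(3 - c) << (2 * (s - 1)));
        kfwd = ((kfwd << 2) | (uint64_t)c) & kmask;
        krc = (krc >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
        ++run;
        if (run >= s)
            shash[i - s + 1] = mix64(sfwd < src ? sfwd : src);
        if (run >= k) {
            kvalid[i - k + 1] = 1;
            khash[i - k + 1] = mix64(kfwd < krc ? kfwd : krc);
        }
    }
    // select k-mers whose minimum s-mer hash sits at offset t (1-based),
    // ties broken toward the smallest offset
    for (int64_t j = 0; j + k <= n; ++j) {
        if (!kvalid[j]) continue;
        int argmin = 0;
        uint64_t best = shash[j];
        for (int w = 1; w < win; ++w) {
            if (shash[j + w] < best) { best = shash[j + w]; argmin = w; }
        }
        if (argmin == t - 1) {
            out.pos.push_back(j);
            out.hash.push_back(khash[j]);
        }
    }
    return out;
}

// [[Rcpp::export]]
DataFrame cpp_syncmers(std::string seq, int k, int s, int t) {
    if (s > k) stop("s must not exceed k");
    if (t < 1 || t > k - s + 1) stop("t must lie in [1, k-s+1]");
    SyncmerVec sv = open_syncmers_core(seq, k, s, t);
    R_xlen_t m = sv.pos.size();
    NumericVector pos(m);
    CharacterVector hash(m);
    for (R_xlen_t i = 0; i < m; ++i) {
        pos[i] = (double)sv.pos[i];
        hash[i] = hash_to_hex(sv.hash[i]);
    }
    return DataFrame::create(_["pos"] = pos, _["hash"] = hash,
                             _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_minimizers(std::string seq, int k, int w) {
    int64_t n = (int64_t)seq.size();
    std::vector<double> opos;
    std::vector<std::string> ohash;
    if (n >= k && w >= 1) {
        int64_t nk = n - k + 1;
        std::vector<char> kvalid(nk, 0);
        std::vector<uint64_t> khash(nk);
        uint64_t kfwd = 0, krc = 0;
        uint64_t kmask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
        int64_t run = 0;
        for (int64_t i = 0; i < n; ++i) {
            int c = base_code(seq[i]);
            if (c < 0) { run = 0; continue; }
            kfwd = ((kfwd << 2) | (uint64_t)c) & kmask;
            krc = (krc >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
            ++run;
            if (run >= k) {
                kvalid[i - k + 1] = 1;
                khash[i - k + 1] = mix64(kfwd < krc ? kfwd : krc);
            }
        }
        int64_t last = -1;
        for (int64_t j = 0; j + w <= nk; ++j) {
            // windows containing any undecodable k-mer are skipped
            bool ok = true;
            int64_t argmin = -1;
            uint64_t best = 0;
            for (int64_t m = j; m < j + w; ++m) {
                if (!kvalid[m]) { ok = false; break; }
                if (argmin < 0 || khash[m] < best) { best = khash[m]; argmin = m; }
            }
            if (!ok) continue;
            if (argmin != last) {
                opos.push_back((double)argmin);
                ohash.push_back(hash_to_hex(khash[argmin]));
                last = argmin;
            }
        }
    }
    return DataFrame::create(_["pos"] = opos, _["hash"] = ohash,
                             _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
CharacterVector cpp_kmer_hashes(std::string seq, int k) {
    int64_t n = (int64_t)seq.size();
    std::vector<std::string> out;
    if (n >= k) {
        uint64_t kfwd = 0, krc = 0;
        uint64_t kmask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
        int64_t run = 0;
        for (int64_t i = 0; i < n; ++i) {
            int c = base_code(seq[i]);
            if (c < 0) { run = 0; continue; }
            kfwd = ((kfwd << 2) | (uint64_t)c) & kmask;
            krc = (krc >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
            ++run;
            if (run >= k)
                out.push_back(hash_to_hex(mix64(kfwd < krc ? kfwd : krc)));
        }
    }
    return wrap(out);
}

// [[Rcpp::export]]
int cpp_link_skew(std::string k1_hash, CharacterVector window, int p) {
    if (window.size() == 0) stop("no candidate: empty window");
    if (p < 1 || p > 64) stop("p must lie in [1, 64]");
    uint64_t h1 = hex_to_hash(k1_hash);
    int besti = 0;
    int best = 65;
    for (R_xlen_t i = 0; i < window.size(); ++i) {
        uint64_t h2 = hex_to_hash(as<std::string>(window[i]));
        int v = popcount_top(h1 ^ h2, p);
        if (v < best) { best = v; besti = (int)i; }
    }
    return besti;  // 0-based; R wrapper shifts
}

// [[Rcpp::export]]
int cpp_link_sum(std::string k1_hash, CharacterVector window, int p) {
    if (window.size() == 0) stop("no candidate: empty window");
    if (p < 1 || p > 64) stop("p must lie in [1, 64]");
    uint64_t h1 = hex_to_hash(k1_hash);
    uint64_t mask = top_mask(p);
    int besti = 0;
    uint64_t best = ~0ULL;
    bool first = true;
    for (R_xlen_t i = 0; i < window.size(); ++i) {
        uint64_t h2 = hex_to_hash(as<std::string>(window[i]));
        uint64_t v = (h1 + h2) & mask;
        if (first || v < best) { best = v; besti = (int)i; first = false; }
    }
    return besti;
}

// [[Rcpp::export]]
std::string cpp_strobemer_hash(std::string h1, std::string h2) {
    uint64_t a = hex_to_hash(h1), b = hex_to_hash(h2);
    return hash_to_hex(a / 2 + b / 2);
}

SeedVec link_seeds_core(const SyncmerVec &sync, int wmin, int wmax, int p,
                        int k, int max_seed_len, bool reverse_iter,
                        int64_t seq_len) {
    (void)seq_len;
    SeedVec out;
    int64_t n = (int64_t)sync.pos.size();
    for (int64_t jj = 0; jj < n; ++jj) {
        int64_t j = reverse_iter ? (n - 1 - jj) : jj;
        uint64_t h1 = sync.hash[j];
        int besti = -1;
        int best = 65;
        // candidate syncmers wmin..wmax positions downstream in iteration
        // order, truncated by the maximum seed span; nearest candidate is
        // scanned first so ties pick the first (leftmost) strobe
        for (int w = wmin; w <= wmax; ++w) {
            int64_t m = reverse_iter ? (j - w) : (j + w);
            if (m < 0 || m >= n) break;
            int64_t span = reverse_iter ? (sync.pos[j] + k - sync.pos[m])
                                        : (sync.pos[m] + k - sync.pos[j]);
            if (span > max_seed_len) break;
            int v = popcount_top(h1 ^ sync.hash[m], p);
            if (v < best) { best = v; besti = (int)(m); }
        }
        if (besti < 0) {
            // no syncmer in the window: single-syncmer fallback (self-link)
            out.hash.push_back(h1 / 2 + h1 / 2);
            out.q_s.push_back(sync.pos[j]);
            out.q_e.push_back(sync.pos[j] + k);
            out.offset.push_back(0);
            out.orient.push_back(reverse_iter ? 1 : 0);
            out.is_single.push_back(1);
        } else {
            uint64_t h2 = sync.hash[besti];
            int64_t a = sync.pos[j], b = sync.pos[besti];
            int64_t lo = reverse_iter ? b : a;
            int64_t hi = reverse_iter ? a : b;
            out.hash.push_back(h1 / 2 + h2 / 2);
            out.q_s.push_back(lo);
            out.q_e.push_back(hi + k);
            out.offset.push_back((int)(hi - lo));
            out.orient.push_back(reverse_iter ? 1 : 0);
            out.is_single.push_back(0);
        }
    }
    return out;
}

static DataFrame seedvec_to_df(const SeedVec &sv) {
    R_xlen_t m = sv.hash.size();
    CharacterVector hash(m);
    NumericVector qs(m), qe(m);
    IntegerVector off(m), o(m), sing(m);
    for (R_xlen_t i = 0; i < m; ++i) {
        hash[i] = hash_to_hex(sv.hash[i]);
        qs[i] = (double)sv.q_s[i];
        qe[i] = (double)sv.q_e[i];
        off[i] = sv.offset[i];
        o[i] = sv.orient[i];
        sing[i] = sv.is_single[i];
    }
    return DataFrame::create(_["hash"] = hash, _["q_s"] = qs, _["q_e"] = qe,
                             _["offset"] = off, _["o"] = o,
                             _["is_single"] = sing,
                             _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_seeds(std::string seq, int k, int s, int t, int wmin, int wmax,
                    int p, int max_seed_len, bool both_orients) {
    SyncmerVec sync = open_syncmers_core(seq, k, s, t);
    SeedVec fwd = link_seeds_core(sync, wmin, wmax, p, k, max_seed_len,
                                  false, (int64_t)seq.size());
    if (both_orients) {
        SeedVec rev = link_seeds_core(sync, wmin, wmax, p, k, max_seed_len,
                                      true, (int64_t)seq.size());
        fwd.hash.insert(fwd.hash.end(), rev.hash.begin(), rev.hash.end());
        fwd.q_s.insert(fwd.q_s.end(), rev.q_s.begin(), rev.q_s.end());
        fwd.q_e.insert(fwd.q_e.end(), rev.q_e.begin(), rev.q_e.end());
        fwd.offset.insert(fwd.offset.end(), rev.offset.begin(), rev.offset.end());
        fwd.orient.insert(fwd.orient.end(), rev.orient.begin(), rev.orient.end());
        fwd.is_single.insert(fwd.is_single.end(), rev.is_single.begin(),
                             rev.is_single.end());
    }
    return seedvec_to_df(fwd);
}
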