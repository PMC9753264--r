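#include <Rcpp.h>
#include <vector>
#include <string>
#include "core.h"

using namespace Rcpp;

// Local (Smith-Waterman) alignment with affine gaps. A gap of length L costs
// gap_open + (L-1) * gap_ext, i.e. the opening penalty covers the first gap
// base. Unaligned read ends become soft clips. Ties during traceback prefer
// diagonal moves; the maximum cell is the first encountered in row-major
// order, making output deterministic.
// [[Rcpp::export]]
List cpp_sw_align(std::string query, std::string ref,
                  int match = 1, int mismatch = 4,
                  int gap_open = 6, int gap_ext = 1) {
    int n = (int)query.size(), m = (int)ref.size();
    if (n == 0 || m == 0)
        return List::create(_["score"] = 0, _["cigar"] = "",
                            _["q_s"] = 0, _["q_e"] = 0,
                            _["r_s"] = 0, _["r_e"] = 0,
                            _["n_mismatch"] = 0, _["n_gap"] = 0,
                            _["edit"] = 0, _["aligned"] = false);
    const int NEG = -1000000000;
    std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
    std::vector<int> E((size_t)(n + 1) * (m + 1), NEG);
    std::vector<int> F((size_t)(n + 1) * (m + 1), NEG);
    // traceback codes for H: 0 stop, 1 diag, 2 from E (gap in query = D),
    // 3 from F (gap in ref = I); for E/F: 1 = extend
    std::vector<unsigned char> TH((size_t)(n + 1) * (m + 1), 0);
    std::vector<unsigned char> TE((size_t)(n + 1) * (m + 1), 0);
    std::vector<unsigned char> TF((size_t)(n + 1) * (m + 1), 0);
    auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        char qc = (char)toupper(query[i - 1]);
        for (int j = 1; j <= m; ++j) {
            char rc = (char)toupper(ref[j - 1]);
            int eo = H[at(i, j - 1)] - gap_open;
            int ee = E[at(i, j - 1)] - gap_ext;
            E[at(i, j)] = eo >= ee ? eo : ee;
            TE[at(i, j)] = eo >= ee ? 0 : 1;
            int fo = H[at(i - 1, j)] - gap_open;
            int fe = F[at(i - 1, j)] - gap_ext;
            F[at(i, j)] = fo >= fe ? fo : fe;
            TF[at(i, j)] = fo >= fe ? 0 : 1;
            int sub = (qc == rc && qc != 'N') ? match : -mismatch;
            int diag = H[at(i - 1, j - 1)] + sub;
            int h = 0; unsigned char th = 0;
            if (diag > h) { h = diag; th = 1; }
            if (E[at(i, j)] > h) { h = E[at(i, j)]; th = 2; }
            if (F[at(i, j)] > h) { h = F[at(i, j)]; th = 3; }
            H[at(i, j)] = h; TH[at(i, j)] = th;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }
    if (best <= 0)
        return List::create(_["score"] = 0, _["cigar"] = "",
                            _["q_s"] = 0, _["q_e"] = 0,
                            _["r_s"] = 0, _["r_e"] = 0,
                            _["n_mismatch"] = 0, _["n_gap"] = 0,
                            _["edit"] = 0, _["aligned"] = false);
    // traceback
    std::vector<std::pair<char, int>> ops;  // reversed
    int i = bi, j = bj, nmis = 0, ngap = 0;
    auto push = [&ops](char op) {
        if (!ops.empty() && ops.back().first == op) ops.back().second++;
        else ops.push_back(std::make_pair(op, 1));
    };
    int state = 0;  // 0 in H, 2 in E, 3 in F
    while (i > 0 && j > 0) {
        if (state == 0) {
            unsigned char th = TH[at(i, j)];
            if (th == 0) break;
            if (th == 1) {
                push('M');
                char qc = (char)toupper(query[i - 1]);
                char rc = (char)toupper(ref[j - 1]);
                if (qc != rc || qc == 'N') ++nmis;
                --i; --j;
            } else {
                state = th;
            }
        } else if (state == 2) {
            push('D'); ++ngap;
            if (TE[at(i, j)] == 0) state = 0;
            --j;
        } else {
            push('I'); ++ngap;
            if (TF[at(i, j)] == 0) state = 0;
            --i;
        }
    }
    int qs = i, rs = j;  // 0-based alignment starts
    std::string cigar;
    if (qs > 0) cigar += std::to_string(qs) + "S";
    for (auto it = ops.rbegin(); it != ops.rend(); ++it)
        cigar += std::to_string(it->second) + std::string(1, it->first);
    if (bi < n) cigar += std::to_string(n - bi) + "S";
    return List::create(_["score"] = best, _["cigar"] = cigar,
                        _["q_s"] = qs, _["q_e"] = bi,
                        _["r_s"] = rs, _["r_e"] = bj,
                        _["n_mismatch"] = nmis, _["n_gap"] = ngap,
                        _["edit"] = nmis + ngap, _["aligned"] = true);
}

// Hamming comparison of a query against ref[offset, offset + |query|).
// Returns ok = FALSE when the window leaves the reference.
// [[Rcpp::export]]
List cpp_hamming(std::string query, std::string ref, double offset,
                 int match = 1, int mismatch = 4) {
    int64_t n = (int64_t)query.size();
    int64_t off = (int64_t)offset;
    if (off < 0 || off + n > (int64_t)ref.size())
        return List::create(_["ok"] = false, _["n_mismatch"] = 0,
                            _["score"] = 0);
    int64_t nmis = 0;
    for (int64_t i = 0; i < n; ++i) {
        char q = (char)toupper(query[i]);
        char r = (char)toupper(ref[off + i]);
        if (q != r || q == 'N') ++nmis;
    }
    double score = (double)(n - nmis) * match - (double)nmis * mismatch;
    return List::create(_["ok"] = true, _["n_mismatch"] = (double)nmis,
                        _["score"] = score);
}
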