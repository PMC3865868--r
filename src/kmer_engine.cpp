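#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3. Numeric order on equal-k codes is
// lexicographic order on the kmer strings, so sorted codes decode to a
// lexicographically sorted table. k <= 32 fits one uint64_t.

static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

static inline uint64_t revcomp_code(uint64_t code, int k) {
    uint64_t rc = 0;
    for (int i = 0; i < k; ++i) {
        rc = (rc << 2) | (3 - (code & 3));
        code >>= 2;
    }
    return rc;
}

static std::string decode_kmer(uint64_t code, int k) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = bases[code & 3];
        code >>= 2;
    }
    return s;
}

// Rolling scan over one read; calls f(canonical_code) for every window
// free of non-ACGT characters.
template <typename F>
static void scan_read(const char* seq, int n, int k, F f) {
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t fwd = 0, rev = 0;
    int valid = 0;  // length of current run of ACGT bases
    for (int i = 0; i < n; ++i) {
        int c = base_code(seq[i]);
        if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)c) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
        if (++valid >= k) f(fwd < rev ? fwd : rev);
    }
}

// [[Rcpp::export(name = ".cpp_count_kmers")]]
List cpp_count_kmers(CharacterVector reads, int k) {
    if (k < 1 || k > 32) stop("k must be between 1 and 32");
    std::unordered_map<uint64_t, double> counts;
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        const char* s = CHAR(STRING_ELT(reads, r));
        int n = (int)LENGTH(STRING_ELT(reads, r));
        scan_read(s, n, k, [&](uint64_t code) { counts[code] += 1.0; });
    }
    std::vector<uint64_t> keys;
    keys.reserve(counts.size());
    for (auto& kv : counts) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    CharacterVector kmer(keys.size());
    NumericVector count(keys.size());
    for (size_t i = 0; i < keys.size(); ++i) {
        kmer[i] = decode_kmer(keys[i], k);
        count[i] = counts[keys[i]];
    }
    return List::create(_["kmer"] = kmer, _["count"] = count);
}

// Per-read count of windows whose canonical kmer is present in the reference
// set, plus which reference kmers were observed anywhere.
// ref_kmers must be canonical, length-k strings.
// [[Rcpp::export(name = ".cpp_screen_reads")]]
List cpp_screen_reads(CharacterVector reads, int k, CharacterVector ref_kmers) {
    if (k < 1 || k > 32) stop("k must be between 1 and 32");
    std::unordered_map<uint64_t, R_xlen_t> ref;
    ref.reserve(ref_kmers.size() * 2);
    for (R_xlen_t i = 0; i < ref_kmers.size(); ++i) {
        const char* s = CHAR(STRING_ELT(ref_kmers, i));
        if ((int)LENGTH(STRING_ELT(ref_kmers, i)) != k)
            stop("reference kmer %d does not have length k", (int)(i + 1));
        uint64_t code = 0;
        for (int j = 0; j < k; ++j) {
            int c = base_code(s[j]);
            if (c < 0) stop("reference kmer %d has a non-ACGT base", (int)(i + 1));
            code = (code << 2) | (uint64_t)c;
        }
        ref[code] = i;
    }
    IntegerVector hits(reads.size());
    LogicalVector observed(ref_kmers.size(), false);
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        const char* s = CHAR(STRING_ELT(reads, r));
        int n = (int)LENGTH(STRING_ELT(reads, r));
        int h = 0;
        scan_read(s, n, k, [&](uint64_t code) {
            auto it = ref.find(code);
            if (it != ref.end()) { ++h; observed[it->second] = true; }
        });
        hits[r] = h;
    }
    return List::create(_["hits"] = hits, _["observed"] = observed);
}

// Leftmost qualifying junction-adaptor window per read. Windows considered:
//   * suffix of the junction overlapping the read start (ov >= min_overlap),
//     reported at position 0;
//   * full junction at interior positions;
//   * prefix of the junction overlapping the read end (ov >= min_overlap).
// A window qualifies when mismatches <= floor(rate * overlap_length).
// Returns 0-based start positions, NA when no window qualifies.
// [[Rcpp::export(name = ".cpp_find_junction")]]
IntegerVector cpp_find_junction(CharacterVector reads, std::string junction,
                                int min_overlap, double max_mismatch_rate) {
    int jl = (int)junction.size();
    if (min_overlap < 1 || min_overlap > jl)
        stop("min_overlap must be in [1, junction length]");
    IntegerVector out(reads.size(), NA_INTEGER);
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        const char* s = CHAR(STRING_ELT(reads, r));
        int n = (int)LENGTH(STRING_ELT(reads, r));
        int best = NA_INTEGER;
        // junction suffix overlapping the read start (clip position 0)
        for (int ov = std::min(jl - 1, n); ov >= min_overlap; --ov) {
            int mm = 0, limit = (int)(max_mismatch_rate * ov);
            for (int i = 0; i < ov && mm <= limit; ++i)
                if (s[i] != junction[jl - ov + i]) ++mm;
            if (mm <= limit) { best = 0; break; }
        }
        if (best == NA_INTEGER) {
            int full_limit = (int)(max_mismatch_rate * jl);
            for (int p = 0; p + jl <= n; ++p) {
                int mm = 0;
                for (int i = 0; i < jl && mm <= full_limit; ++i)
                    if (s[p + i] != junction[i]) ++mm;
                if (mm <= full_limit) { best = p; break; }
            }
        }
        if (best == NA_INTEGER) {
            // junction prefix overlapping the read end; leftmost = longest overlap
            int start_ov = std::min(jl - 1, n - 1);
            for (int ov = start_ov; ov >= min_overlap; --ov) {
                int p = n - ov;
                int mm = 0, limit = (int)(max_mismatch_rate * ov);
                for (int i = 0; i < ov && mm <= limit; ++i)
                    if (s[p + i] != junction[i]) ++mm;
                if (mm <= limit) { best = p; break; }
            }
        }
        out[r] = best;
    }
    return out;
}

// Hamming distance between each string and a fixed pattern of equal length;
// NA where lengths differ.
// [[Rcpp::export(name = ".cpp_hamming")]]
IntegerVector cpp_hamming(CharacterVector strings, std::string pattern) {
    int m = (int)pattern.size();
    IntegerVector out(strings.size(), NA_INTEGER);
    for (R_xlen_t r = 0; r < strings.size(); ++r) {
        if (STRING_ELT(strings, r) == NA_STRING) continue;
        if ((int)LENGTH(STRING_ELT(strings, r)) != m) continue;
        const char* s = CHAR(STRING_ELT(strings, r));
        int mm = 0;
        for (int i = 0; i < m; ++i)
            if (s[i] != pattern[i]) ++mm;
        out[r] = mm;
    }
    return out;
}
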