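#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

// 2-bit encoding; -1 for non-ACGT
static inline int base2bit(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// splitmix64 finalizer: invertible integer mixing
static inline uint64_t mix64(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

// order key of the canonical (min of forward / reverse-complement 2-bit
// codes) k-mer, masked to 53 bits so it is exactly representable in a double
static const uint64_t HASH_MASK = (1ULL << 53) - 1;

struct KmerOcc {
    int start;       // 0-based base position
    bool fwd;        // canonical == forward?
    uint64_t hash;
    bool valid;
};

static void scan_kmers(const std::string &seq, int k, std::vector<KmerOcc> &out) {
    const int n = (int)seq.size();
    const int nk = n - k + 1;
    out.clear();
    if (nk <= 0) return;
    out.resize(nk);
    uint64_t fwd = 0, rev = 0;
    const uint64_t kmask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    const int shift = 2 * (k - 1);
    int run = 0; // valid-base run length
    for (int i = 0; i < n; ++i) {
        int c = base2bit(seq[i]);
        if (c < 0) {
            run = 0; fwd = 0; rev = 0;
        } else {
            fwd = ((fwd << 2) | (uint64_t)c) & kmask;
            rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
            ++run;
        }
        int p = i - k + 1;
        if (p >= 0) {
            KmerOcc &o = out[p];
            o.start = p;
            if (run >= k) {
                uint64_t canon = (fwd <= rev) ? fwd : rev;
                o.fwd = (fwd <= rev);
                o.hash = mix64(canon) & HASH_MASK;
                o.valid = true;
            } else {
                o.valid = false;
            }
        }
    }
}

// [[Rcpp::export]]
DataFrame extract_minimizers_cpp(std::string seq, int w, int k) {
    std::vector<KmerOcc> kmers;
    scan_kmers(seq, k, kmers);
    const int nk = (int)kmers.size();
    std::vector<char> selected(nk > 0 ? nk : 1, 0);
    // every window of w consecutive k-mer positions; ties all selected
    for (int j = 0; j + w <= nk; ++j) {
        uint64_t best = ~0ULL;
        bool any = false;
        for (int i = j; i < j + w; ++i) {
            if (kmers[i].valid && kmers[i].hash < best) { best = kmers[i].hash; any = true; }
        }
        if (!any) continue;
        for (int i = j; i < j + w; ++i)
            if (kmers[i].valid && kmers[i].hash == best) selected[i] = 1;
    }
    std::vector<int> starts;
    std::vector<bool> fwds;
    std::vector<double> hashes;
    for (int i = 0; i < nk; ++i) {
        if (selected[i]) {
            starts.push_back(kmers[i].start);
            fwds.push_back(kmers[i].fwd);
            hashes.push_back((double)kmers[i].hash);
        }
    }
    CharacterVector strand(starts.size());
    for (size_t i = 0; i < fwds.size(); ++i) strand[i] = fwds[i] ? "+" : "-";
    return DataFrame::create(
        _["start"] = wrap(starts),
        _["strand"] = strand,
        _["hash"] = wrap(hashes),
        _["stringsAsFactors"] = false);
}

// order keys for a character vector of k-mers (the shared hash primitive,
// exposed so the brute-force oracle can rank k-mers without reusing the
// sliding-window extraction path); NA for k-mers containing non-ACGT bases
// [[Rcpp::export]]
NumericVector kmer_order_key_cpp(CharacterVector kmers) {
    const int n = kmers.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(kmers[i]);
        const int k = (int)s.size();
        uint64_t fwd = 0, rev = 0;
        bool ok = (k >= 1 && k <= 31);
        const int shift = 2 * (k - 1);
        for (int j = 0; ok && j < k; ++j) {
            int c = base2bit(s[j]);
            if (c < 0) { ok = false; break; }
            fwd = (fwd << 2) | (uint64_t)c;
            rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
        }
        if (!ok) { out[i] = NA_REAL; continue; }
        uint64_t canon = (fwd <= rev) ? fwd : rev;
        out[i] = (double)(mix64(canon) & HASH_MASK);
    }
    return out;
}
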