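#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// 2-bit base encoding (A=0, C=1, G=2, T=3); anything else (e.g. N) is
// invalid and breaks a k-mer window, so windows containing N never match.
// With k <= 15 codes fit comfortably in R's signed 32-bit integers.
static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

static inline uint32_t revcomp_code(uint32_t code, int k) {
    uint32_t rc = 0;
    for (int i = 0; i < k; ++i) {
        rc = (rc << 2) | (3U - (code & 3U));
        code >>= 2;
    }
    return rc;
}

// [[Rcpp::export]]
IntegerVector encode_kmers_cpp(CharacterVector kmers, int k) {
    int n = kmers.size();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        SEXP sx = STRING_ELT(kmers, i);
        if ((int)LENGTH(sx) != k) stop("k-mer %d does not have length %d", i + 1, k);
        const char* s = CHAR(sx);
        uint32_t code = 0;
        for (int j = 0; j < k; ++j) {
            int b = base_code(s[j]);
            if (b < 0) stop("k-mer contains a non-ACGT character: %s", s);
            code = (code << 2) | (uint32_t)b;
        }
        out[i] = (int)code;
    }
    return out;
}

// [[Rcpp::export]]
CharacterVector decode_kmers_cpp(IntegerVector codes, int k) {
    static const char bases[] = "ACGT";
    int n = codes.size();
    CharacterVector out(n);
    std::string buf(k, 'A');
    for (int i = 0; i < n; ++i) {
        uint32_t code = (uint32_t)codes[i];
        for (int j = k - 1; j >= 0; --j) {
            buf[j] = bases[code & 3U];
            code >>= 2;
        }
        out[i] = buf;
    }
    return out;
}

// [[Rcpp::export]]
IntegerVector revcomp_codes_cpp(IntegerVector codes, int k) {
    int n = codes.size();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = (int)revcomp_code((uint32_t)codes[i], k);
    return out;
}

// Count, for each candidate k-mer code, how many foreground and background
// sequences contain it on either strand (gene-level presence, not
// occurrence counts). Returns a matrix with columns fg_with, bg_with.
// [[Rcpp::export]]
IntegerMatrix kmer_presence_counts_codes_cpp(CharacterVector fg_seqs,
                                             CharacterVector bg_seqs,
                                             IntegerVector codes, int k) {
    int ncand = codes.size();
    IntegerMatrix out(ncand, 2);
    colnames(out) = CharacterVector::create("fg_with", "bg_with");
    if (ncand == 0) return out;
    if (k < 1 || k > 15) stop("k-mer length out of supported range");

    // code -> candidate indices (a code may be the forward form of one
    // candidate and the reverse complement of another)
    std::unordered_map<uint32_t, std::vector<int> > lookup;
    lookup.reserve((size_t)ncand * 2);
    for (int i = 0; i < ncand; ++i) {
        uint32_t code = (uint32_t)codes[i];
        lookup[code].push_back(i);
        uint32_t rc = revcomp_code(code, k);
        if (rc != code) lookup[rc].push_back(i);
    }

    std::vector<int> fg_with(ncand, 0), bg_with(ncand, 0);
    std::vector<int> last_seen(ncand, -1);
    const uint32_t mask = (uint32_t)((1ULL << (2 * k)) - 1ULL);

    int nfg = fg_seqs.size(), nbg = bg_seqs.size();
    for (int si = 0; si < nfg + nbg; ++si) {
        SEXP sx = (si < nfg) ? STRING_ELT(fg_seqs, si)
                             : STRING_ELT(bg_seqs, si - nfg);
        const char* s = CHAR(sx);
        int n = LENGTH(sx);
        uint32_t code = 0;
        int valid = 0;  // length of current run of A/C/G/T bases
        for (int i = 0; i < n; ++i) {
            int b = base_code(s[i]);
            if (b < 0) { valid = 0; code = 0; continue; }
            code = ((code << 2) | (uint32_t)b) & mask;
            if (++valid < k) continue;
            std::unordered_map<uint32_t, std::vector<int> >::const_iterator
                it = lookup.find(code);
            if (it == lookup.end()) continue;
            for (size_t j = 0; j < it->second.size(); ++j) {
                int idx = it->second[j];
                if (last_seen[idx] != si) {
                    last_seen[idx] = si;
                    if (si < nfg) fg_with[idx]++; else bg_with[idx]++;
                }
            }
        }
    }

    for (int i = 0; i < ncand; ++i) {
        out(i, 0) = fg_with[i];
        out(i, 1) = bg_with[i];
    }
    return out;
}

// String-candidate convenience wrapper (all candidates share one length).
// [[Rcpp::export]]
IntegerMatrix kmer_presence_counts_cpp(CharacterVector fg_seqs,
                                       CharacterVector bg_seqs,
                                       CharacterVector kmers) {
    if (kmers.size() == 0) {
        IntegerMatrix out(0, 2);
        colnames(out) = CharacterVector::create("fg_with", "bg_with");
        return out;
    }
    int k = LENGTH(STRING_ELT(kmers, 0));
    return kmer_presence_counts_codes_cpp(fg_seqs, bg_seqs,
                                          encode_kmers_cpp(kmers, k), k);
}
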