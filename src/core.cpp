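#include <Rcpp.h>
#include <cstring>
#include <cstdio>
using namespace Rcpp;

// 4-bit code table over the 16-letter nucleotide alphabet (IUPAC + U).
// -1 marks symbols outside the table.
static inline int baseCode(char c) {
    switch (c) {
    case 'A': return 0;  case 'C': return 1;  case 'G': return 2;  case 'T': return 3;
    case 'N': return 4;  case 'R': return 5;  case 'Y': return 6;  case 'S': return 7;
    case 'W': return 8;  case 'K': return 9;  case 'M': return 10; case 'B': return 11;
    case 'D': return 12; case 'H': return 13; case 'V': return 14; case 'U': return 15;
    default:  return -1;
    }
}

static void packWords(const char* s, size_t L, std::vector<uint64_t>& words) {
    words.assign((L + 15) / 16, 0ULL);
    for (size_t i = 0; i < L; ++i) {
        int c = baseCode(s[i]);
        if (c < 0)
            stop("unsupported symbol '%c' at position %d", s[i], (int)(i + 1));
        // base i occupies the (i %% 16)-th nibble from the most-significant end
        words[i / 16] |= ((uint64_t)c) << (60 - 4 * (i % 16));
    }
}

// [[Rcpp::export]]
List pack_sequence_cpp(std::string seq) {
    std::vector<uint64_t> words;
    packWords(seq.c_str(), seq.size(), words);
    CharacterVector out(words.size());
    char buf[17];
    for (size_t w = 0; w < words.size(); ++w) {
        snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)words[w]);
        out[w] = buf;
    }
    return List::create(_["words"] = out, _["length"] = (int)seq.size());
}

// Injective text rendering of the packed form: "<length>:<hex words>".
// Length must be part of the key: a 15-mer ending before an 'A' 16th base
// packs to the same single word as the 16-mer.
// [[Rcpp::export]]
CharacterVector pack_keys_cpp(CharacterVector seqs) {
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    std::vector<uint64_t> words;
    std::string key;
    char buf[24];
    for (R_xlen_t i = 0; i < n; ++i) {
        const char* s = CHAR(STRING_ELT(seqs, i));
        size_t L = std::strlen(s);
        packWords(s, L, words);
        key.clear();
        snprintf(buf, sizeof(buf), "%zu:", L);
        key += buf;
        for (size_t w = 0; w < words.size(); ++w) {
            snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)words[w]);
            key += buf;
        }
        out[i] = key;
    }
    return out;
}

// Hamming distance per pair; NA when lengths differ.
// [[Rcpp::export]]
IntegerVector hamming_cpp(CharacterVector a, CharacterVector b) {
    R_xlen_t n = a.size();
    if (b.size() != n) stop("hamming_cpp: length mismatch");
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char* x = CHAR(STRING_ELT(a, i));
        const char* y = CHAR(STRING_ELT(b, i));
        size_t lx = std::strlen(x), ly = std::strlen(y);
        if (lx != ly) { out[i] = NA_INTEGER; continue; }
        int d = 0;
        for (size_t j = 0; j < lx; ++j) if (x[j] != y[j]) ++d;
        out[i] = d;
    }
    return out;
}

// Byte-wise strict less-than, x[i] < y[i %% len(y)].  Used for merge bounds
// and sortedness checks; R's own "<" on character is collation-dependent and
// mis-handles the control-byte key sentinel.
// [[Rcpp::export]]
LogicalVector str_lt_cpp(CharacterVector x, CharacterVector y) {
    R_xlen_t n = x.size(), m = y.size();
    LogicalVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char* a = CHAR(STRING_ELT(x, i));
        const char* b = CHAR(STRING_ELT(y, m == 1 ? 0 : i % m));
        out[i] = std::strcmp(a, b) < 0;
    }
    return out;
}

static inline bool cmpTight(const char* a, size_t la, const char* b, size_t lb) {
    return la == lb && std::memcmp(a, b, la) == 0;
}
static inline bool cmpLoose(const char* a, size_t la, const char* b, size_t lb) {
    size_t m = la < lb ? la : lb;
    return std::memcmp(a, b, m) == 0;
}
static inline bool cmpTailHamming(const char* a, size_t la, const char* b, size_t lb, int k) {
    if (la != lb) return false;
    int d = 0;
    for (size_t j = 0; j < la; ++j)
        if (a[j] != b[j] && ++d > k) return false;
    return true;
}

static inline bool cmpMode(int mode, const std::string& a, const std::string& b, int k) {
    switch (mode) {
    case 1: return cmpTight(a.c_str(), a.size(), b.c_str(), b.size());
    case 2: return cmpLoose(a.c_str(), a.size(), b.c_str(), b.size());
    default: return cmpTailHamming(a.c_str(), a.size(), b.c_str(), b.size(), k);
    }
}

// Single-pass duplicate scan over one chunk of the key-sorted stream.
// mode: 1 = tight, 2 = loose, 3 = tail-hamming.
// tight/loose compare against the current group representative (the last
// kept unit); tail-hamming compares against the immediate predecessor in
// the sorted stream, kept or not.  Sequences arrive pre-uppercased.
// State carries across chunks.
// [[Rcpp::export]]
List scan_chunk_cpp(CharacterVector left, Nullable<CharacterVector> right,
                    int mode, int k, List state) {
    bool paired = right.isNotNull();
    CharacterVector rt;
    if (paired) rt = right.get();
    R_xlen_t n = left.size();
    if (paired && rt.size() != n) stop("scan_chunk_cpp: mate length mismatch");

    bool has = as<bool>(state["has"]);
    std::string refL = as<std::string>(state["refL"]);
    std::string refR = as<std::string>(state["refR"]);
    std::string predL = as<std::string>(state["predL"]);
    std::string predR = as<std::string>(state["predR"]);

    LogicalVector keep(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string cl = as<std::string>(left[i]);
        std::string cr = paired ? as<std::string>(rt[i]) : std::string();
        bool dup = false;
        if (has) {
            const std::string& bl = (mode == 3) ? predL : refL;
            const std::string& br = (mode == 3) ? predR : refR;
            dup = cmpMode(mode, cl, bl, k) && (!paired || cmpMode(mode, cr, br, k));
        }
        keep[i] = !dup;
        if (!dup && mode != 3) { refL = cl; refR = cr; }
        if (mode == 3) { predL = cl; predR = cr; }
        has = true;
    }
    return List::create(
        _["keep"] = keep,
        _["state"] = List::create(
            _["has"] = has, _["refL"] = refL, _["refR"] = refR,
            _["predL"] = predL, _["predR"] = predR));
}
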