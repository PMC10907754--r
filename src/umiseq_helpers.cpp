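#include <Rcpp.h>
using namespace Rcpp;

// Hamming distance of each string in x against ref; NA when lengths differ.
// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector x, std::string ref) {
    const size_t L = ref.size();
    const R_xlen_t n = x.size();
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        if (x[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
        const char *s = CHAR(x[i]);
        if (std::strlen(s) != L) { out[i] = NA_INTEGER; continue; }
        int d = 0;
        for (size_t j = 0; j < L; ++j) if (s[j] != ref[j]) ++d;
        out[i] = d;
    }
    return out;
}

// Sparse table of substitutions of each equal-length string vs ref:
// (read index, 1-based position, observed character).
// [[Rcpp::export]]
List cpp_mismatch_table(CharacterVector x, std::string ref) {
    const size_t L = ref.size();
    std::vector<int> ridx, rpos;
    std::vector<std::string> rbase;
    for (R_xlen_t i = 0; i < x.size(); ++i) {
        if (x[i] == NA_STRING) continue;
        const char *s = CHAR(x[i]);
        if (std::strlen(s) != L) continue;
        for (size_t j = 0; j < L; ++j) {
            if (s[j] != ref[j]) {
                ridx.push_back((int)(i + 1));
                rpos.push_back((int)(j + 1));
                rbase.push_back(std::string(1, s[j]));
            }
        }
    }
    return List::create(_["read"] = wrap(ridx), _["pos"] = wrap(rpos),
                        _["base"] = wrap(rbase));
}

// Apply single-character substitutions (idx: 1-based row of templ,
// pos: 1-based position, base: replacement character) to a copy of templ.
// Rows must be grouped so repeated edits to one string stay cheap.
// [[Rcpp::export]]
CharacterVector cpp_apply_subs(CharacterVector templ, IntegerVector idx,
                               IntegerVector pos, CharacterVector base) {
    CharacterVector out = clone(templ);
    R_xlen_t k = 0;
    const R_xlen_t m = idx.size();
    while (k < m) {
        const int i = idx[k] - 1;
        std::string s(CHAR(out[i]));
        const int L = (int)s.size();
        while (k < m && idx[k] - 1 == i) {
            const int p = pos[k] - 1;
            if (p >= 0 && p < L) s[p] = CHAR(base[k])[0];
            ++k;
        }
        out[i] = s;
    }
    return out;
}
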