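#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Semi-global (glocal) affine-gap alignment: the pattern is aligned
// end-to-end, the window contributes free leading/trailing overhangs.
// Gap of length k costs open + (k - 1) * extend.
//
// The DP is laid out with the pattern set in the innermost loop so the
// compiler can vectorize across patterns; all patterns must share one
// length per batch (callers score 24-nt barcodes).

static const int16_t NEG = -8000;

static inline int16_t max16(int16_t a, int16_t b) { return a > b ? a : b; }

// scores for all patterns (equal length m) against one window
static void score_window_batch(const std::string& win,
                               const std::vector<char>& patcode, int m,
                               int P, int16_t match, int16_t mismatch,
                               int16_t gap_open, int16_t gap_extend,
                               std::vector<int16_t>& best) {
    const int n = (int)win.size();
    std::vector<int16_t> Hprev((n + 1) * P), Hcur((n + 1) * P);
    std::vector<int16_t> Eprev((n + 1) * P), Ecur((n + 1) * P);
    std::vector<int16_t> Frow(P);
    for (int j = 0; j <= n; ++j) {
        for (int p = 0; p < P; ++p) {
            Hprev[j * P + p] = 0;
            Eprev[j * P + p] = NEG;
        }
    }
    std::fill(best.begin(), best.end(), NEG);
    for (int i = 1; i <= m; ++i) {
        for (int p = 0; p < P; ++p) {
            int16_t e = max16((int16_t)(Hprev[p] - gap_open),
                              (int16_t)(Eprev[p] - gap_extend));
            Ecur[p] = e;
            Hcur[p] = e;
            Frow[p] = NEG;
        }
        const char* prow = patcode.data() + (size_t)(i - 1) * P;
        for (int j = 1; j <= n; ++j) {
            const char wc = win[j - 1];
            const int16_t* Hp = Hprev.data() + (size_t)j * P;
            const int16_t* Hpd = Hprev.data() + (size_t)(j - 1) * P;
            const int16_t* Ep = Eprev.data() + (size_t)j * P;
            const int16_t* Hl = Hcur.data() + (size_t)(j - 1) * P;
            int16_t* Ho = Hcur.data() + (size_t)j * P;
            int16_t* Eo = Ecur.data() + (size_t)j * P;
            int16_t* F = Frow.data();
            for (int p = 0; p < P; ++p) {
                int16_t e = max16((int16_t)(Hp[p] - gap_open),
                                  (int16_t)(Ep[p] - gap_extend));
                int16_t f = max16((int16_t)(Hl[p] - gap_open),
                                  (int16_t)(F[p] - gap_extend));
                int16_t s = (prow[p] == wc) ? match : mismatch;
                int16_t h = max16((int16_t)(Hpd[p] + s), max16(e, f));
                Eo[p] = e;
                F[p] = f;
                Ho[p] = h;
            }
        }
        std::swap(Hprev, Hcur);
        std::swap(Eprev, Ecur);
    }
    for (int j = 0; j <= n; ++j) {
        const int16_t* Hp = Hprev.data() + (size_t)j * P;
        for (int p = 0; p < P; ++p) best[p] = max16(best[p], Hp[p]);
    }
}

// [[Rcpp::export]]
IntegerMatrix cpp_semiglobal_scores(CharacterVector windows,
                                    CharacterVector patterns, int match,
                                    int mismatch, int gap_open,
                                    int gap_extend) {
    const int nw = windows.size();
    const int P = patterns.size();
    if (P == 0 || nw == 0) return IntegerMatrix(nw, P);
    std::vector<std::string> pats(P);
    int m = -1;
    for (int p = 0; p < P; ++p) {
        pats[p] = as<std::string>(patterns[p]);
        if (m < 0) m = (int)pats[p].size();
        else if ((int)pats[p].size() != m)
            stop("all patterns in one batch must have equal length");
    }
    if (m == 0) stop("empty pattern");
    // pattern characters transposed: patcode[(i-1)*P + p] = pats[p][i-1]
    std::vector<char> patcode((size_t)m * P);
    for (int i = 0; i < m; ++i)
        for (int p = 0; p < P; ++p) patcode[(size_t)i * P + p] = pats[p][i];

    IntegerMatrix out(nw, P);
    std::vector<int16_t> best(P);
    for (int w = 0; w < nw; ++w) {
        std::string win = as<std::string>(windows[w]);
        if (win.empty()) stop("empty window");
        score_window_batch(win, patcode, m, P, (int16_t)match,
                           (int16_t)mismatch, (int16_t)gap_open,
                           (int16_t)gap_extend, best);
        for (int p = 0; p < P; ++p) out(w, p) = best[p];
    }
    return out;
}
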