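#include <Rcpp.h>
#include <limits>
#include <string>
#include <vector>

using namespace Rcpp;

// Global pairwise alignment with affine gaps (Needleman-Wunsch-Gotoh).
// A gap of length k costs gapOpen + k * gapExt. Traceback is deterministic:
// ties are broken diagonal > up (gap in the second sequence) > left.

static inline double score3(double a, double b, double c) {
    return std::max(a, std::max(b, c));
}

// [[Rcpp::export(name = ".nwGotohAlign")]]
List nwGotohAlign(std::string ref, std::string orth,
                  double match = 1.0, double mismatch = -1.0,
                  double gapOpen = -10.0, double gapExt = -0.5) {
    const int n = ref.size(), m = orth.size();
    if (n == 0 || m == 0)
        stop("both sequences must be nonempty");
    const double NEG = -std::numeric_limits<double>::infinity();

    // M: ref[i] aligned to orth[j]; X: gap in orth (consume ref);
    // Y: gap in ref (consume orth)
    std::vector<double> M((n + 1) * (m + 1), NEG);
    std::vector<double> X((n + 1) * (m + 1), NEG);
    std::vector<double> Y((n + 1) * (m + 1), NEG);
    const int W = m + 1;
#define IDX(i, j) ((i) * W + (j))

    M[IDX(0, 0)] = 0.0;
    for (int i = 1; i <= n; ++i) X[IDX(i, 0)] = gapOpen + i * gapExt;
    for (int j = 1; j <= m; ++j) Y[IDX(0, j)] = gapOpen + j * gapExt;

    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double s = (ref[i - 1] == orth[j - 1]) ? match : mismatch;
            M[IDX(i, j)] = score3(M[IDX(i - 1, j - 1)],
                                  X[IDX(i - 1, j - 1)],
                                  Y[IDX(i - 1, j - 1)]) + s;
            X[IDX(i, j)] = score3(M[IDX(i - 1, j)] + gapOpen + gapExt,
                                  X[IDX(i - 1, j)] + gapExt,
                                  Y[IDX(i - 1, j)] + gapOpen + gapExt);
            Y[IDX(i, j)] = score3(M[IDX(i, j - 1)] + gapOpen + gapExt,
                                  Y[IDX(i, j - 1)] + gapExt,
                                  X[IDX(i, j - 1)] + gapOpen + gapExt);
        }
    }

    // traceback; state preference M > X > Y at every tie
    std::string outRef, outOrth;
    outRef.reserve(n + m);
    outOrth.reserve(n + m);
    int i = n, j = m;
    double best = score3(M[IDX(n, m)], X[IDX(n, m)], Y[IDX(n, m)]);
    int state;  // 0 = M, 1 = X, 2 = Y
    if (M[IDX(n, m)] == best) state = 0;
    else if (X[IDX(n, m)] == best) state = 1;
    else state = 2;
    const double total = best;

    while (i > 0 || j > 0) {
        if (state == 0) {
            // arrived via diagonal
            double s = (ref[i - 1] == orth[j - 1]) ? match : mismatch;
            double target = M[IDX(i, j)] - s;
            outRef.push_back(ref[i - 1]);
            outOrth.push_back(orth[j - 1]);
            --i; --j;
            if (i == 0 && j == 0) break;
            if (M[IDX(i, j)] == target) state = 0;
            else if (X[IDX(i, j)] == target) state = 1;
            else state = 2;
        } else if (state == 1) {
            double target = X[IDX(i, j)];
            outRef.push_back(ref[i - 1]);
            outOrth.push_back('-');
            --i;
            if (i == 0 && j == 0) break;
            if (M[IDX(i, j)] + gapOpen + gapExt == target) state = 0;
            else if (X[IDX(i, j)] + gapExt == target) state = 1;
            else state = 2;
        } else {
            double target = Y[IDX(i, j)];
            outRef.push_back('-');
            outOrth.push_back(orth[j - 1]);
            --j;
            if (i == 0 && j == 0) break;
            if (M[IDX(i, j)] + gapOpen + gapExt == target) state = 0;
            else if (Y[IDX(i, j)] + gapExt == target) state = 2;
            else state = 1;
        }
    }
#undef IDX

    std::string aRef(outRef.rbegin(), outRef.rend());
    std::string aOrth(outOrth.rbegin(), outOrth.rend());
    return List::create(_["alignedRef"] = aRef,
                        _["alignedOrth"] = aOrth,
                        _["score"] = total);
}
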