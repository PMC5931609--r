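#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Squared Euclidean distance on the torus between grid cells (grid units).
static inline double torus_sq(int r1, int c1, int r2, int c2, int W, int H) {
    double dr = std::abs(r1 - r2);
    dr = std::min(dr, (double)H - dr);
    double dc = std::abs(c1 - c2);
    dc = std::min(dc, (double)W - dc);
    return dr * dr + dc * dc;
}

static inline int best_matching_unit(const NumericMatrix& W, const NumericMatrix& X, int i) {
    const int m = W.nrow(), d = W.ncol();
    int best = 0;
    double bestd = R_PosInf;
    for (int c = 0; c < m; ++c) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
            const double df = W(c, k) - X(i, k);
            s += df * df;
        }
        // strict < keeps the smallest row-major cell index on ties,
        // i.e. the lexicographically smallest (row, col)
        if (s < bestd) { bestd = s; best = c; }
    }
    return best;
}

// Online SOM training. Cells are indexed row-major: cell = row * width + col
// (0-based). Weights start from W0; the caller is responsible for seeding the
// R RNG, which drives the per-epoch Fisher-Yates presentation order.
// [[Rcpp::export]]
NumericMatrix som_train_cpp(NumericMatrix W0, NumericMatrix X,
                            int width, int height, int rounds,
                            double lr_start, double lr_end,
                            double radius_start, double radius_end) {
    const int m = W0.nrow(), d = W0.ncol(), n = X.nrow();
    NumericMatrix W = clone(W0);

    // pairwise squared torus distances between cells, computed once
    std::vector<double> cd((size_t)m * m);
    for (int a = 0; a < m; ++a) {
        const int ra = a / width, ca = a % width;
        for (int b = 0; b < m; ++b) {
            const int rb = b / width, cb = b % width;
            cd[(size_t)a * m + b] = torus_sq(ra, ca, rb, cb, width, height);
        }
    }

    std::vector<int> ord(n);
    for (int e = 0; e < rounds; ++e) {
        const double frac = (rounds > 1) ? (double)e / (rounds - 1) : 0.0;
        double alpha = lr_start * std::pow(lr_end / lr_start, frac);
        if (alpha > 1.0) alpha = 1.0;  // keep w <- w + alpha*(x - w) a contraction
        const double r = radius_start + (radius_end - radius_start) * frac;
        const double r2 = r * r;
        const double sigma2 = 2.0 * (r / 2.0) * (r / 2.0);

        for (int i = 0; i < n; ++i) ord[i] = i;
        for (int i = n - 1; i > 0; --i) {
            int j = (int)std::floor(unif_rand() * (i + 1));
            if (j > i) j = i;
            std::swap(ord[i], ord[j]);
        }

        for (int t = 0; t < n; ++t) {
            const int i = ord[t];
            const int bmu = best_matching_unit(W, X, i);
            const double* cdb = &cd[(size_t)bmu * m];
            for (int c = 0; c < m; ++c) {
                const double dsq = cdb[c];
                if (dsq <= r2) {
                    const double ah = alpha * std::exp(-dsq / sigma2);
                    for (int k = 0; k < d; ++k)
                        W(c, k) += ah * (X(i, k) - W(c, k));
                }
            }
        }
    }
    return W;
}

// Best-matching unit (0-based row-major cell index) for each row of X.
// [[Rcpp::export]]
IntegerVector som_bmu_cpp(NumericMatrix W, NumericMatrix X) {
    const int n = X.nrow();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) out[i] = best_matching_unit(W, X, i);
    return out;
}
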