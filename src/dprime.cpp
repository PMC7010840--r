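#include <Rcpp.h>
using namespace Rcpp;

// Kullback-Leibler specialization of one row against column marginals.
// a: row cells, A: row total, colTot: full column totals, m: grand total.
static double kl_row(const NumericVector& a, double A,
                     const NumericVector& colTot, double m) {
    double d = 0.0;
    for (int j = 0; j < a.size(); ++j) {
        if (a[j] > 0.0) {
            double p = a[j] / A;
            double q = colTot[j] / m;
            d += p * std::log(p / q);
        }
    }
    return d;
}

// Discrete minimum of the row KL given integer marginals: allocate the row
// total one unit at a time to whichever column yields the smallest increase.
// Column totals respond to the allocation (the focal row contributes to
// them), so the objective for column j with b units placed and complement
// total c_j is (b/A) * log(b*m / (A*(c_j + b))); each such term is convex in
// b, which makes the greedy increment exact for the separable problem.
static double dmin_row(const NumericVector& cExcl, int A, double m) {
    int K = cExcl.size();
    std::vector<int> b(K, 0);
    std::vector<double> g(K, 0.0); // current per-column objective value
    for (int step = 0; step < A; ++step) {
        int best = -1;
        double bestDelta = R_PosInf;
        for (int j = 0; j < K; ++j) {
            double bn = b[j] + 1.0;
            double gn = (bn / A) * std::log(bn * m / (A * (cExcl[j] + bn)));
            double delta = gn - g[j];
            if (delta < bestDelta) {
                bestDelta = delta;
                best = j;
            }
        }
        b[best] += 1;
        double bn = b[best];
        g[best] = (bn / A) * std::log(bn * m / (A * (cExcl[best] + bn)));
    }
    double d = 0.0;
    for (int j = 0; j < K; ++j) d += g[j];
    // numerical floor: KL is non-negative, greedy sums can land at -1e-17
    return d < 0.0 ? 0.0 : d;
}

//' Row-wise d' specialization components of an interaction matrix.
//'
//' Returns a matrix with columns d_raw, d_min, d_max, d_prime; one row per
//' input row. Rows with zero total get NA throughout; d_prime is NA when
//' d_max <= d_min (no room for specialization, e.g. a single column).
//' @param M non-negative integer interaction matrix
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix cpp_dfun_rows(const NumericMatrix& M) {
    int n = M.nrow(), K = M.ncol();
    NumericVector colTot(K);
    double m = 0.0;
    for (int j = 0; j < K; ++j) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += M(i, j);
        colTot[j] = s;
        m += s;
    }
    NumericMatrix out(n, 4);
    colnames(out) = CharacterVector::create("d_raw", "d_min", "d_max", "d_prime");
    for (int i = 0; i < n; ++i) {
        NumericVector a = M.row(i);
        double A = 0.0;
        for (int j = 0; j < K; ++j) A += a[j];
        if (A <= 0.0 || m <= 0.0) {
            out(i, 0) = NA_REAL; out(i, 1) = NA_REAL;
            out(i, 2) = NA_REAL; out(i, 3) = NA_REAL;
            continue;
        }
        double draw = kl_row(a, A, colTot, m);
        NumericVector cExcl(K);
        for (int j = 0; j < K; ++j) cExcl[j] = colTot[j] - a[j];
        double dmin = dmin_row(cExcl, (int) std::lround(A), m);
        double dmax = std::log(m / A);
        out(i, 0) = draw;
        out(i, 1) = dmin;
        out(i, 2) = dmax;
        if (K < 2 || dmax - dmin <= 1e-12) {
            out(i, 3) = NA_REAL;
        } else {
            double dp = (draw - dmin) / (dmax - dmin);
            if (dp < 0.0) dp = 0.0;
            if (dp > 1.0) dp = 1.0;
            out(i, 3) = dp;
        }
    }
    return out;
}
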