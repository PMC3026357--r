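#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Low median: for even counts take the lower of the two middle order
// statistics. Deterministic across platforms, matching the R-side contract.
static double low_median(std::vector<double>& v) {
    const size_t n = v.size();
    const size_t k = (n - 1) / 2;
    std::nth_element(v.begin(), v.begin() + k, v.end());
    return v[k];
}

// Median polish of one probeset block: fits value ~ overall + probe + array
// by alternating row/column sweeps of (low) medians. Convergence when the
// total absolute residual changes by less than tol * current total, with a
// hard iteration cap. Returns overall + array effects (the probeset's log2
// expression per array).
static void polish_block(const NumericMatrix& x, int row0, int nrow,
                         double tol, int max_iter, double* out) {
    const int ncol = x.ncol();
    std::vector<double> z((size_t) nrow * ncol);
    for (int j = 0; j < ncol; ++j)
        for (int i = 0; i < nrow; ++i)
            z[(size_t) j * nrow + i] = x(row0 + i, j);

    std::vector<double> row_eff(nrow, 0.0), col_eff(ncol, 0.0);
    double overall = 0.0;
    std::vector<double> buf;
    double oldsum = 0.0;

    for (int iter = 0; iter < max_iter; ++iter) {
        // row sweep
        for (int i = 0; i < nrow; ++i) {
            buf.assign(ncol, 0.0);
            for (int j = 0; j < ncol; ++j) buf[j] = z[(size_t) j * nrow + i];
            const double m = low_median(buf);
            for (int j = 0; j < ncol; ++j) z[(size_t) j * nrow + i] -= m;
            row_eff[i] += m;
        }
        buf.assign(col_eff.begin(), col_eff.end());
        double delta = low_median(buf);
        for (int j = 0; j < ncol; ++j) col_eff[j] -= delta;
        overall += delta;

        // column sweep
        for (int j = 0; j < ncol; ++j) {
            buf.assign(z.begin() + (size_t) j * nrow,
                       z.begin() + (size_t) (j + 1) * nrow);
            const double m = low_median(buf);
            for (int i = 0; i < nrow; ++i) z[(size_t) j * nrow + i] -= m;
            col_eff[j] += m;
        }
        buf.assign(row_eff.begin(), row_eff.end());
        delta = low_median(buf);
        for (int i = 0; i < nrow; ++i) row_eff[i] -= delta;
        overall += delta;

        double newsum = 0.0;
        for (size_t k = 0; k < z.size(); ++k) newsum += std::fabs(z[k]);
        if (newsum == 0.0 || std::fabs(newsum - oldsum) < tol * newsum)
            break;
        oldsum = newsum;
    }
    for (int j = 0; j < ncol; ++j) out[j] = overall + col_eff[j];
}

// [[Rcpp::export(name = ".medianPolishBlocks")]]
NumericMatrix median_polish_blocks(NumericMatrix x, IntegerVector block_start,
                                   IntegerVector block_len, double tol,
                                   int max_iter) {
    const int nblock = block_start.size();
    NumericMatrix out(nblock, x.ncol());
    std::vector<double> row((size_t) x.ncol());
    for (int b = 0; b < nblock; ++b) {
        polish_block(x, block_start[b], block_len[b], tol, max_iter,
                     row.data());
        for (int j = 0; j < x.ncol(); ++j) out(b, j) = row[j];
    }
    return out;
}
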