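#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Maximal circular two-segment split statistic.
// Arcs are (i, j] with 0 <= i < j <= n; the statistic compares the arc mean
// with the complement mean, standardised by sqrt(1/k + 1/(n-k)). Both arcs
// must contain at least min_width points. Ties resolve to the first (i, j)
// in scan order (i ascending, then j).
static void scan_max(const std::vector<double>& x, int min_width,
                     double& best, int& bi, int& bj) {
    int n = (int)x.size();
    std::vector<double> S(n + 1, 0.0);
    for (int t = 0; t < n; ++t) S[t + 1] = S[t] + x[t];
    best = -1.0; bi = -1; bj = -1;
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j <= n; ++j) {
            int k = j - i;
            int m = n - k;
            if (k < min_width || m < min_width) continue;
            double diff = (S[j] - S[i]) / k - (S[n] - S[j] + S[i]) / m;
            double z = std::fabs(diff) / std::sqrt(1.0 / k + 1.0 / m);
            if (z > best) { best = z; bi = i; bj = j; }
        }
    }
}

// [[Rcpp::export(name = ".cbs_max_stat")]]
List cbs_max_stat(NumericVector x, int min_width) {
    std::vector<double> v(x.begin(), x.end());
    double best; int bi, bj;
    scan_max(v, min_width, best, bi, bj);
    if (bi < 0)
        return List::create(_["stat"] = NA_REAL, _["i"] = NA_INTEGER,
                            _["j"] = NA_INTEGER);
    return List::create(_["stat"] = best, _["i"] = bi, _["j"] = bj);
}

// Permutation significance for the maximal split statistic. `perms` holds
// one permutation of 1..n per row. Permutations stop early once enough
// exceedances have accumulated to rule out significance at `alpha`
// (p = (1 + exceed) / (1 + nperm) <= alpha).
// [[Rcpp::export(name = ".cbs_scan")]]
List cbs_scan(NumericVector x, int min_width, IntegerMatrix perms,
              double alpha) {
    std::vector<double> v(x.begin(), x.end());
    double best; int bi, bj;
    scan_max(v, min_width, best, bi, bj);
    if (bi < 0)
        return List::create(_["stat"] = NA_REAL, _["i"] = NA_INTEGER,
                            _["j"] = NA_INTEGER, _["p"] = NA_REAL,
                            _["significant"] = false);
    int nperm = perms.nrow();
    int n = (int)v.size();
    int cap = (int)std::floor(alpha * (1.0 + nperm) - 1.0 + 1e-9);
    int exceed = 0, done = 0;
    std::vector<double> xp(n);
    for (int p = 0; p < nperm; ++p) {
        for (int t = 0; t < n; ++t) xp[t] = v[perms(p, t) - 1];
        double b; int i2, j2;
        scan_max(xp, min_width, b, i2, j2);
        ++done;
        if (b >= best - 1e-12) ++exceed;
        if (exceed > cap) break;
    }
    double pval = (1.0 + exceed) / (1.0 + done);
    bool sig = (done == nperm) && (exceed <= cap);
    return List::create(_["stat"] = best, _["i"] = bi, _["j"] = bj,
                        _["p"] = pval, _["significant"] = sig);
}
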