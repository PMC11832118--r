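#include <Rcpp.h>
using namespace Rcpp;

// PCIT trio elimination over a correlation matrix.
//
// For every unordered trio (x, y, z) the three first-order partial
// correlations are computed, e.g. r_xy.z = (r_xy - r_xz*r_yz) /
// sqrt((1 - r_xz^2)(1 - r_yz^2)), and a data-driven tolerance
// eps = mean(|r_xy.z/r_xy|, |r_xz.y/r_xz|, |r_yz.x/r_yz|).
// Within the trio, pair (x, y) is eliminated iff
// |r_xy| <= |eps*r_xz| AND |r_xy| <= |eps*r_yz|.
// A pair is significant overall iff no trio eliminates it.
//
// Guards (mirrored bit-for-bit by the R brute-force oracle):
//  - a tolerance ratio with |direct r| < 1e-12 contributes 0 to eps;
//  - a trio with eps == 0 eliminates nothing (degenerate, e.g. an
//    all-zero correlation structure).
//
// The caller is responsible for rejecting |r| == 1 off-diagonal.

static inline double partial_corr(double rxy, double rxz, double ryz) {
    return (rxy - rxz * ryz) / std::sqrt((1.0 - rxz * rxz) * (1.0 - ryz * ryz));
}

static inline double tol_ratio(double partial, double direct) {
    if (std::fabs(direct) < 1e-12) return 0.0;
    return std::fabs(partial / direct);
}

// [[Rcpp::export(name = ".pcit_mask_cpp")]]
LogicalMatrix pcit_mask_cpp(NumericMatrix r) {
    const int n = r.nrow();
    LogicalMatrix elim(n, n);

    for (int i = 0; i < n - 2; ++i) {
        for (int j = i + 1; j < n - 1; ++j) {
            const double rij = r(i, j);
            for (int k = j + 1; k < n; ++k) {
                const double rik = r(i, k);
                const double rjk = r(j, k);

                const double pij = partial_corr(rij, rik, rjk);
                const double pik = partial_corr(rik, rij, rjk);
                const double pjk = partial_corr(rjk, rij, rik);

                const double eps = (tol_ratio(pij, rij) +
                                    tol_ratio(pik, rik) +
                                    tol_ratio(pjk, rjk)) / 3.0;
                if (eps > 0.0) {
                    if (std::fabs(rij) <= std::fabs(eps * rik) &&
                        std::fabs(rij) <= std::fabs(eps * rjk)) {
                        elim(i, j) = true;
                        elim(j, i) = true;
                    }
                    if (std::fabs(rik) <= std::fabs(eps * rij) &&
                        std::fabs(rik) <= std::fabs(eps * rjk)) {
                        elim(i, k) = true;
                        elim(k, i) = true;
                    }
                    if (std::fabs(rjk) <= std::fabs(eps * rij) &&
                        std::fabs(rjk) <= std::fabs(eps * rik)) {
                        elim(j, k) = true;
                        elim(k, j) = true;
                    }
                }
            }
        }
    }

    LogicalMatrix sig(n, n);
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j)
            sig(i, j) = (i != j) && !elim(i, j);
    return sig;
}
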