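#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Contrast-weighted pair-distance histogram over all j < k pairs.
// Self-pairs are excluded. Bin i (1-based) covers [(i-1)*dr, i*dr); dr is
// chosen as dmax*(1+1e-9)/nbins so the largest observed distance falls in
// the last bin.
// [[Rcpp::export]]
List pair_hist_cpp(NumericMatrix pos, NumericVector w, int nbins) {
    const int n = pos.nrow();
    if (n < 2) stop("pair histogram needs at least two points");
    if (nbins < 1) stop("nbins must be >= 1");
    std::vector<double> x(n), y(n), z(n);
    for (int i = 0; i < n; ++i) {
        x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    }
    double dmax2 = 0.0;
    for (int j = 0; j < n - 1; ++j) {
        for (int k = j + 1; k < n; ++k) {
            const double dx = x[j] - x[k], dy = y[j] - y[k], dz = z[j] - z[k];
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 > dmax2) dmax2 = d2;
        }
    }
    const double dmax = std::sqrt(dmax2);
    if (dmax <= 0.0) stop("all points coincide: zero maximum distance");
    const double dr = dmax * (1.0 + 1e-9) / nbins;
    NumericVector p(nbins);
    for (int j = 0; j < n - 1; ++j) {
        for (int k = j + 1; k < n; ++k) {
            const double dx = x[j] - x[k], dy = y[j] - y[k], dz = z[j] - z[k];
            const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
            int idx = (int)(d / dr);
            if (idx >= nbins) idx = nbins - 1;
            p[idx] += w[j] * w[k];
        }
    }
    return List::create(_["p"] = p, _["dmax"] = dmax, _["dr"] = dr);
}

// Polydisperse pair-distance histogram: every pair distance d contributes
// at each size-scale node s_m as d*s_m with weight w_j*w_k*sw_m, binned on a
// common grid spanning dmax*max(s).
// [[Rcpp::export]]
List pair_hist_poly_cpp(NumericMatrix pos, NumericVector w, int nbins,
                        NumericVector scales, NumericVector sweights) {
    const int n = pos.nrow();
    const int m = scales.size();
    if (n < 2) stop("pair histogram needs at least two points");
    if (m < 1 || sweights.size() != m)
        stop("scales and sweights must be non-empty and equal length");
    std::vector<double> x(n), y(n), z(n);
    for (int i = 0; i < n; ++i) {
        x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2);
    }
    double dmax2 = 0.0;
    for (int j = 0; j < n - 1; ++j) {
        for (int k = j + 1; k < n; ++k) {
            const double dx = x[j] - x[k], dy = y[j] - y[k], dz = z[j] - z[k];
            const double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 > dmax2) dmax2 = d2;
        }
    }
    const double dmax = std::sqrt(dmax2);
    if (dmax <= 0.0) stop("all points coincide: zero maximum distance");
    double smax = scales[0];
    for (int i = 1; i < m; ++i) if (scales[i] > smax) smax = scales[i];
    const double rmax = dmax * smax;
    const double dr = rmax * (1.0 + 1e-9) / nbins;
    NumericVector p(nbins);
    for (int j = 0; j < n - 1; ++j) {
        for (int k = j + 1; k < n; ++k) {
            const double dx = x[j] - x[k], dy = y[j] - y[k], dz = z[j] - z[k];
            const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
            const double wp = w[j] * w[k];
            for (int i = 0; i < m; ++i) {
                int idx = (int)(d * scales[i] / dr);
                if (idx >= nbins) idx = nbins - 1;
                p[idx] += wp * sweights[i];
            }
        }
    }
    return List::create(_["p"] = p, _["dmax"] = rmax, _["dr"] = dr);
}
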