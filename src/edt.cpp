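#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Exact squared Euclidean distance transform of a 3-D site set
// (Felzenszwalb & Huttenlocher, separable lower-envelope-of-parabolas).
// Sample positions along an axis are i * s (anisotropic spacing supported),
// so returned distances are squared physical distances.

static const double INF = std::numeric_limits<double>::infinity();

// One 1-D pass: f holds squared distances so far, spacing s, length n.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double s) {
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        if (f[q] == INF) continue;
        double xq = q * s;
        while (true) {
            if (f[v[k]] == INF) { // no finite parabola yet
                if (k > 0) { --k; continue; }
                v[k] = q; z[k] = -INF; z[k + 1] = INF;
                break;
            }
            double xv = v[k] * s;
            double sIntersect = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) /
                                (2 * xq - 2 * xv);
            if (sIntersect <= z[k]) {
                --k;
            } else {
                ++k;
                v[k] = q;
                z[k] = sIntersect;
                z[k + 1] = INF;
                break;
            }
        }
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double xq = q * s;
        while (z[k + 1] < xq) ++k;
        if (f[v[k]] == INF) { d[q] = INF; continue; }
        double diff = xq - v[k] * s;
        d[q] = diff * diff + f[v[k]];
    }
}

// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector sites, IntegerVector dim,
                        NumericVector spacing) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    // init: 0 at sites, INF elsewhere
    for (R_xlen_t i = 0; i < n; ++i) out[i] = sites[i] ? 0.0 : INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x (fastest-varying index)
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
            for (int i = 0; i < nx; ++i) f[i] = out[base + i];
            dt1d(f, d, v, z, nx, spacing[0]);
            for (int i = 0; i < nx; ++i) out[base + i] = d[i];
        }
    // pass along y
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + i;
            for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
            dt1d(f, d, v, z, ny, spacing[1]);
            for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
        }
    // pass along z
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)j * nx + i;
            for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nxy];
            dt1d(f, d, v, z, nz, spacing[2]);
            for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nxy] = d[k];
        }
    out.attr("dim") = dim;
    return out;
}
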