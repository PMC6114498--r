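#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// ---- cubic convolution (Keys, a = -0.5) -----------------------------------
// Interpolating kernel; reproduces constants and linear ramps exactly.

static inline double keys_w(double t) {
    const double a = -0.5;
    t = std::fabs(t);
    if (t <= 1.0) return (a + 2.0) * t * t * t - (a + 3.0) * t * t + 1.0;
    if (t < 2.0)  return a * t * t * t - 5.0 * a * t * t + 8.0 * a * t - 4.0 * a;
    return 0.0;
}

static inline int clampi(int i, int lo, int hi) {
    return i < lo ? lo : (i > hi ? hi : i);
}

// Sample a scalar grid at one physical point with a separable tricubic kernel.
static double tricubic_at(const double *v, const int *d,
                          const double *sp, const double *orig,
                          double px, double py, double pz) {
    double x = (px - orig[0]) / sp[0];
    double y = (py - orig[1]) / sp[1];
    double z = (pz - orig[2]) / sp[2];
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    double wx[4], wy[4], wz[4];
    for (int m = 0; m < 4; ++m) {
        wx[m] = keys_w(x - (i0 - 1 + m));
        wy[m] = keys_w(y - (j0 - 1 + m));
        wz[m] = keys_w(z - (k0 - 1 + m));
    }
    const R_xlen_t n1 = d[0], n12 = (R_xlen_t)d[0] * d[1];
    double acc = 0.0;
    for (int mk = 0; mk < 4; ++mk) {
        int k = clampi(k0 - 1 + mk, 0, d[2] - 1);
        double acck = 0.0;
        for (int mj = 0; mj < 4; ++mj) {
            int j = clampi(j0 - 1 + mj, 0, d[1] - 1);
            const double *row = v + (R_xlen_t)j * n1 + (R_xlen_t)k * n12;
            double accj = 0.0;
            for (int mi = 0; mi < 4; ++mi) {
                int i = clampi(i0 - 1 + mi, 0, d[0] - 1);
                accj += wx[mi] * row[i];
            }
            acck += wy[mj] * accj;
        }
        acc += wz[mk] * acck;
    }
    return acc;
}

// [[Rcpp::export]]
NumericVector cpp_sample_tricubic(NumericVector vol, IntegerVector dim,
                                  NumericVector spacing, NumericVector origin,
                                  NumericMatrix pts) {
    const int d[3] = {dim[0], dim[1], dim[2]};
    const double sp[3] = {spacing[0], spacing[1], spacing[2]};
    const double orig[3] = {origin[0], origin[1], origin[2]};
    R_xlen_t n = pts.nrow();
    NumericVector out(n);
    const double *v = REAL(vol);
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = tricubic_at(v, d, sp, orig, pts(i, 0), pts(i, 1), pts(i, 2));
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_resample_tricubic(NumericVector vol, IntegerVector dim,
                                    NumericVector spacing, NumericVector origin,
                                    IntegerVector odim, NumericVector ospacing,
                                    NumericVector oorigin) {
    const int d[3] = {dim[0], dim[1], dim[2]};
    const double sp[3] = {spacing[0], spacing[1], spacing[2]};
    const double orig[3] = {origin[0], origin[1], origin[2]};
    const int od[3] = {odim[0], odim[1], odim[2]};
    NumericVector out((R_xlen_t)od[0] * od[1] * od[2]);
    const double *v = REAL(vol);
    double *o = REAL(out);
    R_xlen_t idx = 0;
    for (int k = 0; k < od[2]; ++k) {
        double pz = oorigin[2] + k * ospacing[2];
        for (int j = 0; j < od[1]; ++j) {
            double py = oorigin[1] + j * ospacing[1];
            for (int i = 0; i < od[0]; ++i, ++idx)
                o[idx] = tricubic_at(v, d, sp, orig,
                                     oorigin[0] + i * ospacing[0], py, pz);
        }
    }
    return out;
}

// ---- exact Euclidean distance transform -----------------------------------
// Felzenszwalb & Huttenlocher squared-distance transform, separable, with
// per-axis physical sample spacing (anisotropic voxels honored).

static void dt1d(std::vector<double> &f, std::vector<double> &out, double h,
                 std::vector<int> &v, std::vector<double> &z) {
    const int n = (int)f.size();
    const double INF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        double xq = q * h;
        double s;
        while (true) {
            double xv = v[k] * h;
            s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
            if (s <= z[k]) { --k; } else break;
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        double xq = q * h;
        while (z[k + 1] < xq) ++k;
        double dx = xq - v[k] * h;
        out[q] = dx * dx + f[v[k]];
    }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim,
                      NumericVector spacing) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n1 = nx, n12 = (R_xlen_t)nx * ny, N = n12 * nz;
    // large finite stand-in for "inside, distance unknown": keeps the
    // lower-envelope intersections finite (true infinities produce NaNs)
    const double BIG = 1e20;
    NumericVector out(N);
    double *g = REAL(out);
    for (R_xlen_t i = 0; i < N; ++i) g[i] = mask[i] ? BIG : 0.0;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), o(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // x passes
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            double *col = g + (R_xlen_t)j * n1 + (R_xlen_t)k * n12;
            f.assign(col, col + nx);
            f.resize(nx);
            o.resize(nx);
            dt1d(f, o, spacing[0], v, z);
            for (int i = 0; i < nx; ++i) col[i] = o[i];
        }
    // y passes
    f.resize(ny); o.resize(ny);
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            double *base = g + i + (R_xlen_t)k * n12;
            for (int j = 0; j < ny; ++j) f[j] = base[(R_xlen_t)j * n1];
            dt1d(f, o, spacing[1], v, z);
            for (int j = 0; j < ny; ++j) base[(R_xlen_t)j * n1] = o[j];
        }
    // z passes
    f.resize(nz); o.resize(nz);
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            double *base = g + i + (R_xlen_t)j * n1;
            for (int k = 0; k < nz; ++k) f[k] = base[(R_xlen_t)k * n12];
            dt1d(f, o, spacing[2], v, z);
            for (int k = 0; k < nz; ++k) base[(R_xlen_t)k * n12] = o[k];
        }
    for (R_xlen_t i = 0; i < N; ++i) g[i] = std::sqrt(g[i]);
    return out;
}

// ---- spatial brush ---------------------------------------------------------
// Paint sigmoid HU profiles centered at a sequence of stroke points, keeping
// the per-voxel maximum of current and painted value.

// [[Rcpp::export]]
NumericVector cpp_paint_strokes(NumericVector vol, IntegerVector dim,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix centers, NumericVector radii,
                                double C, double a, double support) {
    NumericVector out = clone(vol);
    double *v = REAL(out);
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const R_xlen_t n1 = nx, n12 = (R_xlen_t)nx * ny;
    const int m = centers.nrow();
    for (int s = 0; s < m; ++s) {
        const double cx = centers(s, 0), cy = centers(s, 1), cz = centers(s, 2);
        const double R = radii[s];
        const double half = support * R;
        int i0 = clampi((int)std::ceil((cx - half - origin[0]) / spacing[0]), 0, nx - 1);
        int i1 = clampi((int)std::floor((cx + half - origin[0]) / spacing[0]), 0, nx - 1);
        int j0 = clampi((int)std::ceil((cy - half - origin[1]) / spacing[1]), 0, ny - 1);
        int j1 = clampi((int)std::floor((cy + half - origin[1]) / spacing[1]), 0, ny - 1);
        int k0 = clampi((int)std::ceil((cz - half - origin[2]) / spacing[2]), 0, nz - 1);
        int k1 = clampi((int)std::floor((cz + half - origin[2]) / spacing[2]), 0, nz - 1);
        for (int k = k0; k <= k1; ++k) {
            double dz = origin[2] + k * spacing[2] - cz;
            for (int j = j0; j <= j1; ++j) {
                double dy = origin[1] + j * spacing[1] - cy;
                double *row = v + (R_xlen_t)j * n1 + (R_xlen_t)k * n12;
                for (int i = i0; i <= i1; ++i) {
                    double dx = origin[0] + i * spacing[0] - cx;
                    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
                    double val = C + C * (0.5 - 1.0 / (1.0 + std::exp(-a * (r - R))));
                    if (val > row[i]) row[i] = val;
                }
            }
        }
    }
    return out;
}
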