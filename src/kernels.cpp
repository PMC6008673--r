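// Low-level voxel kernels. All neighbourhood operators use clamp-to-edge
// addressing, matching the package-wide border policy.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Separable 1D convolution along one axis of an n-d array (any number of
// trailing axes, e.g. a channel axis, is handled transparently because the
// kernel only moves along `axis`).
// [[Rcpp::export(name = ".conv_axis")]]
NumericVector conv_axis(NumericVector a, IntegerVector dims, int axis,
                        NumericVector k) {
  int L = dims.size();
  if (axis < 0 || axis >= L) stop("axis out of range");
  int klen = k.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  int r = klen / 2;
  std::vector<R_xlen_t> stride(L);
  R_xlen_t n = 1;
  for (int i = 0; i < L; ++i) { stride[i] = n; n *= dims[i]; }
  NumericVector out(n);
  int d = dims[axis];
  R_xlen_t s = stride[axis];
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    int c = (int)((idx / s) % d);
    R_xlen_t base = idx - (R_xlen_t)c * s;
    double acc = 0.0;
    for (int j = 0; j < klen; ++j) {
      int cc = clampi(c + j - r, 0, d - 1);
      acc += k[j] * a[base + (R_xlen_t)cc * s];
    }
    out[idx] = acc;
  }
  return out;
}

// 3x3x3 median: the 14th order statistic of the 27 clamped neighbours.
// [[Rcpp::export(name = ".median27")]]
NumericVector median27(NumericVector a, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  double buf[27];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int m = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = clampi(x + dx, 0, nx - 1);
              int yy = clampi(y + dy, 0, ny - 1);
              int zz = clampi(z + dz, 0, nz - 1);
              buf[m++] = a[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
            }
        std::nth_element(buf, buf + 13, buf + 27);
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = buf[13];
      }
  return out;
}

// min/max/average over the clamped (2r+1)^3 box; op: 0 min, 1 max, 2 avg.
// [[Rcpp::export(name = ".region_filter")]]
NumericVector region_filter(NumericVector a, IntegerVector dims, int op,
                            int radius) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  int r = radius;
  double count = (double)(2 * r + 1) * (2 * r + 1) * (2 * r + 1);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = (op == 0) ? R_PosInf : (op == 1) ? R_NegInf : 0.0;
        for (int dz = -r; dz <= r; ++dz)
          for (int dy = -r; dy <= r; ++dy)
            for (int dx = -r; dx <= r; ++dx) {
              int xx = clampi(x + dx, 0, nx - 1);
              int yy = clampi(y + dy, 0, ny - 1);
              int zz = clampi(z + dz, 0, nz - 1);
              double v = a[xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
              if (op == 0) acc = std::min(acc, v);
              else if (op == 1) acc = std::max(acc, v);
              else acc += v;
            }
        if (op == 2) acc /= count;
        out[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = acc;
      }
  return out;
}

// One-dimensional squared-distance pass: lower envelope of the parabolas
// q -> (x-q)^2 + f(q) (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = R_NegInf;
  z[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance transform: input holds the preparation pass
// (0 at feature voxels, a large finite sentinel elsewhere); one separable
// pass per axis, in the order given (0-based axis indices).
// [[Rcpp::export(name = ".edt_squared")]]
NumericVector edt_squared(NumericVector a, IntegerVector dims,
                          IntegerVector order) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector cur = clone(a);
  int nd[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  int maxd = std::max(nx, std::max(ny, nz));
  std::vector<double> f(maxd), d(maxd), z(maxd + 1);
  std::vector<int> v(maxd);
  for (int oi = 0; oi < order.size(); ++oi) {
    int ax = order[oi];
    if (ax < 0 || ax > 2) stop("axis out of range");
    int len = nd[ax];
    if (len == 1) continue;
    R_xlen_t s = stride[ax];
    // iterate over all lines perpendicular to `ax`
    int oa1 = (ax + 1) % 3, oa2 = (ax + 2) % 3;
    for (int j2 = 0; j2 < nd[oa2]; ++j2)
      for (int j1 = 0; j1 < nd[oa1]; ++j1) {
        R_xlen_t base = (R_xlen_t)j1 * stride[oa1] + (R_xlen_t)j2 * stride[oa2];
        for (int q = 0; q < len; ++q) f[q] = cur[base + (R_xlen_t)q * s];
        dt1d(f, d, v, z, len);
        for (int q = 0; q < len; ++q) cur[base + (R_xlen_t)q * s] = d[q];
      }
  }
  (void)n;
  return cur;
}
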