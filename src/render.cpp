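// CPU volume ray-caster: perspective camera, front-to-back compositing,
// trilinear reconstruction with clamp-to-edge addressing.
#include <Rcpp.h>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

struct Vec3 { double x, y, z; };

static inline Vec3 v3(double x, double y, double z) { Vec3 v = {x, y, z}; return v; }
static inline Vec3 add3(Vec3 a, Vec3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline Vec3 scale3(Vec3 a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
static inline double dot3(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline double norm3(Vec3 a) { return std::sqrt(dot3(a, a)); }

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Trilinear sample over voxel centres (voxel i spans [i, i+1); centre i+0.5).
static double sample_tri(const double* a, int nx, int ny, int nz, Vec3 p) {
  double qx = clampd(p.x - 0.5, 0.0, (double)(nx - 1));
  double qy = clampd(p.y - 0.5, 0.0, (double)(ny - 1));
  double qz = clampd(p.z - 0.5, 0.0, (double)(nz - 1));
  int x0 = (int)std::floor(qx), y0 = (int)std::floor(qy), z0 = (int)std::floor(qz);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  double fx = qx - x0, fy = qy - y0, fz = qz - z0;
  #define AT(i, j, k) a[(i) + (R_xlen_t)nx * ((j) + (R_xlen_t)ny * (k))]
  double c00 = AT(x0, y0, z0) * (1 - fx) + AT(x1, y0, z0) * fx;
  double c10 = AT(x0, y1, z0) * (1 - fx) + AT(x1, y1, z0) * fx;
  double c01 = AT(x0, y0, z1) * (1 - fx) + AT(x1, y0, z1) * fx;
  double c11 = AT(x0, y1, z1) * (1 - fx) + AT(x1, y1, z1) * fx;
  #undef AT
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static Vec3 gradient_tri(const double* a, int nx, int ny, int nz, Vec3 p) {
  double h = 1.0;
  return v3(
    (sample_tri(a, nx, ny, nz, v3(p.x + h, p.y, p.z)) -
     sample_tri(a, nx, ny, nz, v3(p.x - h, p.y, p.z))) / (2 * h),
    (sample_tri(a, nx, ny, nz, v3(p.x, p.y + h, p.z)) -
     sample_tri(a, nx, ny, nz, v3(p.x, p.y - h, p.z))) / (2 * h),
    (sample_tri(a, nx, ny, nz, v3(p.x, p.y, p.z + h)) -
     sample_tri(a, nx, ny, nz, v3(p.x, p.y, p.z - h))) / (2 * h));
}

// Slab intersection of a ray with the box [0,nx]x[0,ny]x[0,nz].
static bool ray_box(Vec3 o, Vec3 d, Vec3 hi, double& tn, double& tf) {
  tn = 0.0;
  tf = R_PosInf;
  double oo[3] = {o.x, o.y, o.z};
  double dd[3] = {d.x, d.y, d.z};
  double bb[3] = {hi.x, hi.y, hi.z};
  for (int i = 0; i < 3; ++i) {
    if (std::fabs(dd[i]) < 1e-12) {
      if (oo[i] < 0.0 || oo[i] > bb[i]) return false;
    } else {
      double t0 = (0.0 - oo[i]) / dd[i];
      double t1 = (bb[i] - oo[i]) / dd[i];
      if (t0 > t1) std::swap(t0, t1);
      tn = std::max(tn, t0);
      tf = std::min(tf, t1);
      if (tn > tf) return false;
    }
  }
  return true;
}

// mode: 0 translucent, 1 solid, 2 solid with curvature colouring,
// 3 edge/step. Output is W*H*4 (x fastest, RGBA planes last).
// [[Rcpp::export(name = ".render_core")]]
NumericVector render_core(NumericVector vol, IntegerVector dims,
                          NumericVector aux, bool hasAux, double auxScale,
                          int mode, double threshold, double opacityScale,
                          double step, NumericVector bg, NumericVector eye,
                          NumericVector rightv, NumericVector upv,
                          NumericVector fwd, double tanHalfFov, int W, int H) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* a = REAL(vol);
  const double* ax = hasAux ? REAL(aux) : (const double*)0;
  Vec3 o = v3(eye[0], eye[1], eye[2]);
  Vec3 R = v3(rightv[0], rightv[1], rightv[2]);
  Vec3 U = v3(upv[0], upv[1], upv[2]);
  Vec3 F = v3(fwd[0], fwd[1], fwd[2]);
  Vec3 boxhi = v3((double)nx, (double)ny, (double)nz);
  double aspect = (double)W / (double)H;
  NumericVector out((R_xlen_t)W * H * 4);
  R_xlen_t npix = (R_xlen_t)W * H;

  for (int j = 0; j < H; ++j) {
    for (int i = 0; i < W; ++i) {
      double sx = ((i + 0.5) / W * 2.0 - 1.0) * tanHalfFov * aspect;
      double sy = (1.0 - (j + 0.5) / H * 2.0) * tanHalfFov;
      Vec3 d = add3(F, add3(scale3(R, sx), scale3(U, sy)));
      double dn = norm3(d);
      d = scale3(d, 1.0 / dn);
      double tn, tf;
      double r = bg[0], g = bg[1], b = bg[2], alpha = 0.0;
      bool done = false;
      if (ray_box(o, d, boxhi, tn, tf)) {
        if (mode == 0) {
          double C = 0.0, A = 0.0;
          for (double t = tn + 0.5 * step; t < tf; t += step) {
            Vec3 p = add3(o, scale3(d, t));
            double val = sample_tri(a, nx, ny, nz, p);
            double ai = clampd(val * opacityScale * step, 0.0, 1.0);
            C += (1.0 - A) * ai * val;
            A += (1.0 - A) * ai;
            if (A >= 0.999) break;
          }
          r = C + (1.0 - A) * bg[0];
          g = C + (1.0 - A) * bg[1];
          b = C + (1.0 - A) * bg[2];
          alpha = A;
          done = true;
        } else {
          for (double t = tn + 0.5 * step; t < tf; t += step) {
            Vec3 p = add3(o, scale3(d, t));
            double val = sample_tri(a, nx, ny, nz, p);
            if (val >= threshold) {
              if (mode == 3) {
                r = g = b = 1.0;
              } else {
                Vec3 gr = gradient_tri(a, nx, ny, nz, p);
                double gn = norm3(gr);
                double shade = 1.0;
                if (gn > 1e-12) {
                  Vec3 n = scale3(gr, -1.0 / gn);
                  double lam = std::max(0.0, dot3(n, scale3(d, -1.0)));
                  shade = 0.1 + 0.9 * lam;
                }
                if (mode == 2 && ax) {
                  double c = sample_tri(ax, nx, ny, nz, p);
                  double tcol = (auxScale > 0) ? clampd(c / auxScale, -1.0, 1.0)
                                               : 0.0;
                  double rr, gg, bb2;
                  if (tcol < 0) { rr = 1.0 + tcol; gg = 1.0 + tcol; bb2 = 1.0; }
                  else { rr = 1.0; gg = 1.0 - tcol; bb2 = 1.0 - tcol; }
                  r = shade * rr; g = shade * gg; b = shade * bb2;
                } else {
                  r = g = b = shade;
                }
              }
              alpha = 1.0;
              done = true;
              break;
            }
          }
          if (!done) { r = bg[0]; g = bg[1]; b = bg[2]; alpha = 0.0; }
        }
      }
      R_xlen_t px = (R_xlen_t)i + (R_xlen_t)W * j;
      out[px] = r;
      out[px + npix] = g;
      out[px + 2 * npix] = b;
      out[px + 3 * npix] = alpha;
    }
  }
  return out;
}
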