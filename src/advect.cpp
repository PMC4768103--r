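#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gridded, time-resolved velocity field sampler and backward RK4 integrator.
// Conventions (fixed package-wide): positions mm, time ms, velocity cm/s.
// 1 cm/s = 0.01 mm/ms, applied here so trajectories are integrated in mm/ms.
//
// Field layout: column-major array with dim (nx, ny, nz, nt, 3).
// Voxel centers at origin + index * spacing (0-based indices).
// Spatial queries outside the voxel-center hull return zero velocity and
// raise an out-of-domain flag; temporal queries must lie within the span.

struct Field {
  const double *v;
  int nx, ny, nz, nt;
  double ox, oy, oz, dx, dy, dz;
  const double *times;

  inline double at(int i, int j, int k, int t, int c) const {
    return v[i + (size_t)nx * (j + (size_t)ny * (k + (size_t)nz * (t + (size_t)nt * c)))];
  }
};

// trilinear sample of one timeframe; returns false when out of the spatial domain
static inline bool sample_frame(const Field &f, double x, double y, double z,
                                int t, double out[3]) {
  double fx = (x - f.ox) / f.dx;
  double fy = (y - f.oy) / f.dy;
  double fz = (z - f.oz) / f.dz;
  const double eps = 1e-9;
  if (fx < -eps || fy < -eps || fz < -eps ||
      fx > f.nx - 1 + eps || fy > f.ny - 1 + eps || fz > f.nz - 1 + eps) {
    out[0] = out[1] = out[2] = 0.0;
    return false;
  }
  if (fx < 0) fx = 0; if (fy < 0) fy = 0; if (fz < 0) fz = 0;
  if (fx > f.nx - 1) fx = f.nx - 1;
  if (fy > f.ny - 1) fy = f.ny - 1;
  if (fz > f.nz - 1) fz = f.nz - 1;

  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
  if (i0 > f.nx - 2) i0 = f.nx - 2; if (i0 < 0) i0 = 0;
  if (j0 > f.ny - 2) j0 = f.ny - 2; if (j0 < 0) j0 = 0;
  if (k0 > f.nz - 2) k0 = f.nz - 2; if (k0 < 0) k0 = 0;
  int i1 = (f.nx > 1) ? i0 + 1 : i0;
  int j1 = (f.ny > 1) ? j0 + 1 : j0;
  int k1 = (f.nz > 1) ? k0 + 1 : k0;
  double wx = (f.nx > 1) ? fx - i0 : 0.0;
  double wy = (f.ny > 1) ? fy - j0 : 0.0;
  double wz = (f.nz > 1) ? fz - k0 : 0.0;

  for (int c = 0; c < 3; ++c) {
    double c00 = f.at(i0, j0, k0, t, c) * (1 - wx) + f.at(i1, j0, k0, t, c) * wx;
    double c10 = f.at(i0, j1, k0, t, c) * (1 - wx) + f.at(i1, j1, k0, t, c) * wx;
    double c01 = f.at(i0, j0, k1, t, c) * (1 - wx) + f.at(i1, j0, k1, t, c) * wx;
    double c11 = f.at(i0, j1, k1, t, c) * (1 - wx) + f.at(i1, j1, k1, t, c) * wx;
    double c0 = c00 * (1 - wy) + c10 * wy;
    double c1 = c01 * (1 - wy) + c11 * wy;
    out[c] = c0 * (1 - wz) + c1 * wz;
  }
  return true;
}

// space-time sample: trilinear in space, linear in time (cm/s)
static inline bool sample_xt(const Field &f, double x, double y, double z,
                             double t, double out[3]) {
  // locate bracketing frames (times strictly increasing)
  int lo = 0, hi = f.nt - 1;
  const double teps = 1e-9;
  if (t <= f.times[0] + teps) { lo = hi = 0; }
  else if (t >= f.times[f.nt - 1] - teps) { lo = hi = f.nt - 1; }
  else {
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (f.times[mid] <= t) lo = mid; else hi = mid;
    }
  }
  if (lo == hi) return sample_frame(f, x, y, z, lo, out);
  double w = (t - f.times[lo]) / (f.times[hi] - f.times[lo]);
  double a[3], b[3];
  bool ina = sample_frame(f, x, y, z, lo, a);
  bool inb = sample_frame(f, x, y, z, hi, b);
  for (int c = 0; c < 3; ++c) out[c] = a[c] * (1 - w) + b[c] * w;
  return ina && inb;
}

// [[Rcpp::export]]
List sample_velocity_cpp(NumericVector field, IntegerVector dim,
                         NumericVector spacing, NumericVector origin,
                         NumericVector times, NumericMatrix pts, double t) {
  Field f;
  f.v = REAL(field);
  f.nx = dim[0]; f.ny = dim[1]; f.nz = dim[2]; f.nt = dim[3];
  f.ox = origin[0]; f.oy = origin[1]; f.oz = origin[2];
  f.dx = spacing[0]; f.dy = spacing[1]; f.dz = spacing[2];
  f.times = REAL(times);

  int n = pts.nrow();
  NumericMatrix out(n, 3);
  LogicalVector oob(n);
  double vv[3];
  for (int p = 0; p < n; ++p) {
    bool in = sample_xt(f, pts(p, 0), pts(p, 1), pts(p, 2), t, vv);
    out(p, 0) = vv[0]; out(p, 1) = vv[1]; out(p, 2) = vv[2];
    oob[p] = !in;
  }
  return List::create(_["v"] = out, _["out_of_domain"] = oob);
}

// Classic RK4, integrated backwards from t_seed to t_origin with step `step`
// (ms, positive); the final partial step is shortened to land exactly on
// t_origin. A particle is flagged when any stage sample leaves the spatial
// domain at any step (velocity there is zero: the particle freezes).
// [[Rcpp::export]]
List advect_rk4_cpp(NumericVector field, IntegerVector dim,
                    NumericVector spacing, NumericVector origin,
                    NumericVector times, NumericMatrix pts,
                    double t_seed, double t_origin, double step) {
  Field f;
  f.v = REAL(field);
  f.nx = dim[0]; f.ny = dim[1]; f.nz = dim[2]; f.nt = dim[3];
  f.ox = origin[0]; f.oy = origin[1]; f.oz = origin[2];
  f.dx = spacing[0]; f.dy = spacing[1]; f.dz = spacing[2];
  f.times = REAL(times);

  const double UNIT = 0.01; // cm/s -> mm/ms
  int n = pts.nrow();
  NumericMatrix end(n, 3);
  LogicalVector oob(n);

  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    double t = t_seed;
    bool flagged = false;
    double k1[3], k2[3], k3[3], k4[3];
    while (t > t_origin + 1e-9) {
      double h = step;
      if (t - h < t_origin) h = t - t_origin;
      double hn = -h; // backward
      bool in1 = sample_xt(f, x, y, z, t, k1);
      bool in2 = sample_xt(f, x + 0.5 * hn * UNIT * k1[0],
                           y + 0.5 * hn * UNIT * k1[1],
                           z + 0.5 * hn * UNIT * k1[2], t + 0.5 * hn, k2);
      bool in3 = sample_xt(f, x + 0.5 * hn * UNIT * k2[0],
                           y + 0.5 * hn * UNIT * k2[1],
                           z + 0.5 * hn * UNIT * k2[2], t + 0.5 * hn, k3);
      bool in4 = sample_xt(f, x + hn * UNIT * k3[0],
                           y + hn * UNIT * k3[1],
                           z + hn * UNIT * k3[2], t + hn, k4);
      if (!(in1 && in2 && in3 && in4)) flagged = true;
      x += hn * UNIT * (k1[0] + 2 * k2[0] + 2 * k3[0] + k4[0]) / 6.0;
      y += hn * UNIT * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1]) / 6.0;
      z += hn * UNIT * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2]) / 6.0;
      t += hn;
    }
    end(p, 0) = x; end(p, 1) = y; end(p, 2) = z;
    oob[p] = flagged;
  }
  return List::create(_["end"] = end, _["out_of_domain"] = oob);
}
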