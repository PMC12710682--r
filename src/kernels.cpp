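// Low-level kernels for cylinder-network Monte Carlo:
//  - point-in-network queries under the 27-periodic-image convention
//  - network generation at a target blood volume fraction (R's RNG)
//  - off-resonance field of cylinder perturbers (exact and on a lattice)
//  - random-walk phase evolution with impermeable vessel barriers
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double EPS_DIR = 1e-12;

// Image offsets: img in 0..26 -> shift components in {-1,0,1}
static inline void img_shift(int img, int &sx, int &sy, int &sz) {
  sx = img % 3 - 1;
  sy = (img / 3) % 3 - 1;
  sz = img / 9 - 1;
}

static inline double wrap1(double x, double edge) {
  x -= edge * std::floor(x / edge);
  if (x >= edge) x -= edge; // guard against floor rounding
  return x;
}

// Clip infinite line a + t*d to axis-aligned box [lo, hi]; false if disjoint.
static bool clip_line(const double a[3], const double d[3],
                      const double lo[3], const double hi[3],
                      double &t0, double &t1) {
  t0 = -1e30; t1 = 1e30;
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(d[k]) < EPS_DIR) {
      if (a[k] < lo[k] || a[k] > hi[k]) return false;
    } else {
      double u0 = (lo[k] - a[k]) / d[k], u1 = (hi[k] - a[k]) / d[k];
      if (u0 > u1) std::swap(u0, u1);
      t0 = std::max(t0, u0);
      t1 = std::min(t1, u1);
      if (t0 > t1) return false;
    }
  }
  return true;
}

// Spatial hash over the unit cell: each cell lists (cylinder, image) pairs
// whose axis line passes within R + cell half-diagonal of the cell center.
struct CellIndex {
  int m = 1;
  double h = 0.0, edge = 0.0;
  std::vector<std::vector<int>> cells; // encoded cyl * 27 + img

  inline int cell_of(double x, double y, double z) const {
    int i = std::min(m - 1, (int)(x / h));
    int j = std::min(m - 1, (int)(y / h));
    int k = std::min(m - 1, (int)(z / h));
    return (k * m + j) * m + i;
  }
};

static void build_cell_index(CellIndex &ci,
                             const std::vector<double> &ax,
                             const std::vector<double> &ay,
                             const std::vector<double> &az,
                             const std::vector<double> &dx,
                             const std::vector<double> &dy,
                             const std::vector<double> &dz,
                             double R, double edge) {
  int ncyl = (int)ax.size();
  ci.edge = edge;
  ci.m = std::max(1, std::min(128, (int)std::floor(edge / std::max(2.0, R))));
  ci.h = edge / ci.m;
  ci.cells.assign((size_t)ci.m * ci.m * ci.m, std::vector<int>());
  const double thr = R + 0.5 * ci.h * std::sqrt(3.0) + 1e-9;
  const double thr2 = thr * thr;
  double lo[3] = {-thr, -thr, -thr};
  double hi[3] = {edge + thr, edge + thr, edge + thr};
  for (int c = 0; c < ncyl; ++c) {
    double d[3] = {dx[c], dy[c], dz[c]};
    for (int img = 0; img < 27; ++img) {
      int sx, sy, sz;
      img_shift(img, sx, sy, sz);
      double a[3] = {ax[c] + sx * edge, ay[c] + sy * edge, az[c] + sz * edge};
      double t0, t1;
      if (!clip_line(a, d, lo, hi, t0, t1)) continue;
      double p0[3], p1[3], bl[3], bh[3];
      for (int k = 0; k < 3; ++k) {
        p0[k] = a[k] + t0 * d[k];
        p1[k] = a[k] + t1 * d[k];
        bl[k] = std::min(p0[k], p1[k]) - thr;
        bh[k] = std::max(p0[k], p1[k]) + thr;
      }
      int il = std::max(0, (int)std::floor(bl[0] / ci.h));
      int ih = std::min(ci.m - 1, (int)std::floor(bh[0] / ci.h));
      int jl = std::max(0, (int)std::floor(bl[1] / ci.h));
      int jh = std::min(ci.m - 1, (int)std::floor(bh[1] / ci.h));
      int kl = std::max(0, (int)std::floor(bl[2] / ci.h));
      int kh = std::min(ci.m - 1, (int)std::floor(bh[2] / ci.h));
      int code = c * 27 + img;
      for (int k = kl; k <= kh; ++k)
        for (int j = jl; j <= jh; ++j)
          for (int i = il; i <= ih; ++i) {
            double cx = (i + 0.5) * ci.h - a[0];
            double cy = (j + 0.5) * ci.h - a[1];
            double cz = (k + 0.5) * ci.h - a[2];
            double t = cx * d[0] + cy * d[1] + cz * d[2];
            double rho2 = cx * cx + cy * cy + cz * cz - t * t;
            if (rho2 <= thr2)
              ci.cells[(size_t)(k * ci.m + j) * ci.m + i].push_back(code);
          }
    }
  }
}

static inline bool point_inside(const CellIndex &ci,
                                const std::vector<double> &ax,
                                const std::vector<double> &ay,
                                const std::vector<double> &az,
                                const std::vector<double> &dx,
                                const std::vector<double> &dy,
                                const std::vector<double> &dz,
                                double R2, double edge,
                                double px, double py, double pz) {
  const std::vector<int> &lst = ci.cells[ci.cell_of(px, py, pz)];
  for (size_t q = 0; q < lst.size(); ++q) {
    int code = lst[q];
    int c = code / 27, img = code % 27;
    int sx, sy, sz;
    img_shift(img, sx, sy, sz);
    double vx = px - sx * edge - ax[c];
    double vy = py - sy * edge - ay[c];
    double vz = pz - sz * edge - az[c];
    double t = vx * dx[c] + vy * dy[c] + vz * dz[c];
    double rho2 = vx * vx + vy * vy + vz * vz - t * t;
    if (rho2 <= R2) return true;
  }
  return false;
}

static void mat_to_cols(const NumericMatrix &m, std::vector<double> &x,
                        std::vector<double> &y, std::vector<double> &z) {
  int n = m.nrow();
  x.resize(n); y.resize(n); z.resize(n);
  for (int i = 0; i < n; ++i) { x[i] = m(i, 0); y[i] = m(i, 1); z[i] = m(i, 2); }
}

// [[Rcpp::export]]
LogicalVector cpp_point_in_network(NumericMatrix axis, NumericMatrix dir,
                                   double radius, double edge,
                                   NumericMatrix pts) {
  int npts = pts.nrow(), ncyl = axis.nrow();
  LogicalVector out(npts);
  if (ncyl == 0) return out;
  std::vector<double> ax, ay, az, dx, dy, dz;
  mat_to_cols(axis, ax, ay, az);
  mat_to_cols(dir, dx, dy, dz);
  CellIndex ci;
  build_cell_index(ci, ax, ay, az, dx, dy, dz, radius, edge);
  double R2 = radius * radius;
  for (int i = 0; i < npts; ++i) {
    double px = wrap1(pts(i, 0), edge);
    double py = wrap1(pts(i, 1), edge);
    double pz = wrap1(pts(i, 2), edge);
    out[i] = point_inside(ci, ax, ay, az, dx, dy, dz, R2, edge, px, py, pz);
  }
  return out;
}

// Marsaglia (1972) uniform sampling on the unit sphere.
static inline void marsaglia_dir(double &x, double &y, double &z) {
  double u1, u2, s;
  do {
    u1 = 2.0 * unif_rand() - 1.0;
    u2 = 2.0 * unif_rand() - 1.0;
    s = u1 * u1 + u2 * u2;
  } while (s >= 1.0 || s == 0.0);
  double f = std::sqrt(1.0 - s);
  x = 2.0 * u1 * f;
  y = 2.0 * u2 * f;
  z = 1.0 - 2.0 * s;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_sphere(int n) {
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double x, y, z;
    marsaglia_dir(x, y, z);
    out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
  }
  return out;
}

// Cylinders are added until the Monte-Carlo intravascular fraction (over a
// fixed panel of n_test uniform points, drawn first) crosses the target.
// [[Rcpp::export]]
List cpp_generate_network(double edge, double target, double radius,
                          int max_cyl, int n_test) {
  std::vector<double> tx(n_test), ty(n_test), tz(n_test);
  for (int i = 0; i < n_test; ++i) {
    tx[i] = unif_rand() * edge;
    ty[i] = unif_rand() * edge;
    tz[i] = unif_rand() * edge;
  }
  std::vector<char> inside(n_test, 0);
  std::vector<double> ax, ay, az, dx, dy, dz;
  long cnt = 0;
  double frac = 0.0, R2 = radius * radius;
  if (target > 0.0) {
    while (frac < target) {
      if ((int)ax.size() >= max_cyl)
        stop("generation-failure: max_cylinders (%d) reached at fraction %.4f",
             max_cyl, frac);
      double a0 = unif_rand() * edge, a1 = unif_rand() * edge,
             a2 = unif_rand() * edge;
      double d0, d1, d2;
      marsaglia_dir(d0, d1, d2);
      ax.push_back(a0); ay.push_back(a1); az.push_back(a2);
      dx.push_back(d0); dy.push_back(d1); dz.push_back(d2);
      for (int i = 0; i < n_test; ++i) {
        if (inside[i]) continue;
        for (int img = 0; img < 27; ++img) {
          int sx, sy, sz;
          img_shift(img, sx, sy, sz);
          double vx = tx[i] - sx * edge - a0;
          double vy = ty[i] - sy * edge - a1;
          double vz = tz[i] - sz * edge - a2;
          double t = vx * d0 + vy * d1 + vz * d2;
          double rho2 = vx * vx + vy * vy + vz * vz - t * t;
          if (rho2 <= R2) { inside[i] = 1; ++cnt; break; }
        }
      }
      frac = (double)cnt / n_test;
    }
  }
  int ncyl = (int)ax.size();
  NumericMatrix A(ncyl, 3), D(ncyl, 3);
  for (int c = 0; c < ncyl; ++c) {
    A(c, 0) = ax[c]; A(c, 1) = ay[c]; A(c, 2) = az[c];
    D(c, 0) = dx[c]; D(c, 1) = dy[c]; D(c, 2) = dz[c];
  }
  return List::create(_["axis"] = A, _["direction"] = D,
                      _["achieved_fraction"] = frac,
                      _["n_test_points"] = n_test);
}

// Per-cylinder geometric precomputation for the dipole field.
// base = gamma * B0 * delta_chi (rad/s). B0 along +z.
struct CylField {
  double ax, ay, az, dx, dy, dz;
  double e1x, e1y, e1z, e2x, e2y, e2z;
  double extcoef;  // base/2 * sin^2(theta) * R^2
  double intcoef;  // base * (3 cos^2(theta) - 1) / 6
  bool has_ext;
};

static void precompute_field(std::vector<CylField> &cf,
                             const NumericMatrix &axis,
                             const NumericMatrix &dir,
                             double radius, double base) {
  int ncyl = axis.nrow();
  cf.resize(ncyl);
  for (int c = 0; c < ncyl; ++c) {
    CylField &f = cf[c];
    f.ax = axis(c, 0); f.ay = axis(c, 1); f.az = axis(c, 2);
    f.dx = dir(c, 0); f.dy = dir(c, 1); f.dz = dir(c, 2);
    double cz = f.dz; // cos(theta) with B0 || +z
    double sin2 = 1.0 - cz * cz;
    f.intcoef = base * (3.0 * cz * cz - 1.0) / 6.0;
    f.extcoef = 0.5 * base * sin2 * radius * radius;
    // e1 = unit projection of z-hat on the plane normal to the axis
    double bx = -cz * f.dx, by = -cz * f.dy, bz = 1.0 - cz * f.dz;
    double nb = std::sqrt(bx * bx + by * by + bz * bz);
    if (nb < EPS_DIR) {
      f.has_ext = false;
      f.e1x = f.e1y = f.e1z = f.e2x = f.e2y = f.e2z = 0.0;
    } else {
      f.has_ext = true;
      f.e1x = bx / nb; f.e1y = by / nb; f.e1z = bz / nb;
      f.e2x = f.dy * f.e1z - f.dz * f.e1y;
      f.e2y = f.dz * f.e1x - f.dx * f.e1z;
      f.e2z = f.dx * f.e1y - f.dy * f.e1x;
    }
  }
}

// Field of one (cylinder, image) at point p; R2 = radius^2, c2 = cutoff^2.
static inline double cyl_field_at(const CylField &f, double R2, double c2,
                                  double px, double py, double pz) {
  double vx = px - f.ax, vy = py - f.ay, vz = pz - f.az;
  double t = vx * f.dx + vy * f.dy + vz * f.dz;
  double rho2 = vx * vx + vy * vy + vz * vz - t * t;
  if (rho2 <= R2) return f.intcoef;
  if (rho2 > c2) return 0.0;
  if (!f.has_ext) return 0.0;
  double c1 = vx * f.e1x + vy * f.e1y + vz * f.e1z;
  double cc2 = vx * f.e2x + vy * f.e2y + vz * f.e2z;
  return f.extcoef * (c1 * c1 - cc2 * cc2) / (rho2 * rho2);
}

// Single cylinder, no periodic images (the closed-form oracle).
// [[Rcpp::export]]
NumericVector cpp_cylinder_field_single(NumericMatrix pts, NumericVector a,
                                        NumericVector d, double radius,
                                        double base) {
  NumericMatrix A(1, 3), D(1, 3);
  for (int k = 0; k < 3; ++k) { A(0, k) = a[k]; D(0, k) = d[k]; }
  std::vector<CylField> cf;
  precompute_field(cf, A, D, radius, base);
  double R2 = radius * radius;
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cyl_field_at(cf[0], R2, 1e60, pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// Exact superposition over all cylinders and their 27 periodic images.
// [[Rcpp::export]]
NumericVector cpp_exact_field(NumericMatrix axis, NumericMatrix dir,
                              double radius, double edge, double base,
                              NumericMatrix pts) {
  int n = pts.nrow(), ncyl = axis.nrow();
  NumericVector out(n);
  if (ncyl == 0) return out;
  std::vector<CylField> cf;
  precompute_field(cf, axis, dir, radius, base);
  double R2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    double px = wrap1(pts(i, 0), edge);
    double py = wrap1(pts(i, 1), edge);
    double pz = wrap1(pts(i, 2), edge);
    double acc = 0.0;
    for (int c = 0; c < ncyl; ++c)
      for (int img = 0; img < 27; ++img) {
        int sx, sy, sz;
        img_shift(img, sx, sy, sz);
        acc += cyl_field_at(cf[c], R2, 1e60, px - sx * edge, py - sy * edge,
                            pz - sz * edge);
      }
    out[i] = acc;
  }
  return out;
}

// Lattice of n^3 nodes at coordinates i * (edge/n), i = 0..n-1 (periodic).
// Per (cylinder, image) the infinite line is clipped to the grid box inflated
// by the cutoff and only nodes inside the clipped bounding box are visited.
// [[Rcpp::export]]
NumericVector cpp_build_field_grid(NumericMatrix axis, NumericMatrix dir,
                                   double radius, double edge, int n,
                                   double base, double cutoff) {
  NumericVector out((R_xlen_t)n * n * n);
  int ncyl = axis.nrow();
  if (ncyl == 0) return out;
  std::vector<CylField> cf;
  precompute_field(cf, axis, dir, radius, base);
  double g = edge / n;
  double R2 = radius * radius;
  bool finite_cut = R_FINITE(cutoff);
  double cut = finite_cut ? cutoff : 2.0 * edge; // covers the box fully
  double c2 = finite_cut ? cutoff * cutoff : 1e60;
  double span = (n - 1) * g;
  double lo[3] = {-cut, -cut, -cut};
  double hi[3] = {span + cut, span + cut, span + cut};
  for (int c = 0; c < ncyl; ++c) {
    double d[3] = {cf[c].dx, cf[c].dy, cf[c].dz};
    for (int img = 0; img < 27; ++img) {
      int sx, sy, sz;
      img_shift(img, sx, sy, sz);
      double a[3] = {cf[c].ax + sx * edge, cf[c].ay + sy * edge,
                     cf[c].az + sz * edge};
      double t0, t1;
      if (!clip_line(a, d, lo, hi, t0, t1)) continue;
      double bl[3], bh[3];
      for (int k = 0; k < 3; ++k) {
        double p0 = a[k] + t0 * d[k], p1 = a[k] + t1 * d[k];
        bl[k] = std::min(p0, p1) - cut;
        bh[k] = std::max(p0, p1) + cut;
      }
      int il = std::max(0, (int)std::ceil(bl[0] / g));
      int ih = std::min(n - 1, (int)std::floor(bh[0] / g));
      int jl = std::max(0, (int)std::ceil(bl[1] / g));
      int jh = std::min(n - 1, (int)std::floor(bh[1] / g));
      int kl = std::max(0, (int)std::ceil(bl[2] / g));
      int kh = std::min(n - 1, (int)std::floor(bh[2] / g));
      // shift the cylinder so node coordinates can be used directly
      CylField fs = cf[c];
      fs.ax = a[0]; fs.ay = a[1]; fs.az = a[2];
      for (int k = kl; k <= kh; ++k) {
        double z = k * g;
        for (int j = jl; j <= jh; ++j) {
          double y = j * g;
          R_xlen_t rowbase = ((R_xlen_t)k * n + j) * n;
          for (int i = il; i <= ih; ++i)
            out[rowbase + i] += cyl_field_at(fs, R2, c2, i * g, y, z);
        }
      }
    }
  }
  return out;
}

// Trilinear interpolation on the periodic lattice.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vals, int n, double edge,
                            NumericMatrix pts) {
  int npts = pts.nrow();
  NumericVector out(npts);
  double g = edge / n;
  for (int i = 0; i < npts; ++i) {
    double u = wrap1(pts(i, 0), edge) / g;
    double v = wrap1(pts(i, 1), edge) / g;
    double w = wrap1(pts(i, 2), edge) / g;
    int i0 = std::min(n - 1, (int)u), j0 = std::min(n - 1, (int)v),
        k0 = std::min(n - 1, (int)w);
    double fu = u - i0, fv = v - j0, fw = w - k0;
    int i1 = (i0 + 1) % n, j1 = (j0 + 1) % n, k1 = (k0 + 1) % n;
    double acc = 0.0;
    for (int dk = 0; dk < 2; ++dk) {
      int kk = dk ? k1 : k0;
      double wk = dk ? fw : 1.0 - fw;
      for (int dj = 0; dj < 2; ++dj) {
        int jj = dj ? j1 : j0;
        double wj = dj ? fv : 1.0 - fv;
        for (int di = 0; di < 2; ++di) {
          int ii = di ? i1 : i0;
          double wi = di ? fu : 1.0 - fu;
          acc += wi * wj * wk * vals[((R_xlen_t)kk * n + jj) * n + ii];
        }
      }
    }
    out[i] = acc;
  }
  return out;
}

// Rejection sampling of extravascular positions (uniform in tissue).
// [[Rcpp::export]]
NumericMatrix cpp_seed_spins(NumericMatrix axis, NumericMatrix dir,
                             double radius, double edge, int n_spins) {
  int ncyl = axis.nrow();
  NumericMatrix out(n_spins, 3);
  if (ncyl == 0) {
    for (int i = 0; i < n_spins; ++i) {
      out(i, 0) = unif_rand() * edge;
      out(i, 1) = unif_rand() * edge;
      out(i, 2) = unif_rand() * edge;
    }
    return out;
  }
  std::vector<double> ax, ay, az, dx, dy, dz;
  mat_to_cols(axis, ax, ay, az);
  mat_to_cols(dir, dx, dy, dz);
  CellIndex ci;
  build_cell_index(ci, ax, ay, az, dx, dy, dz, radius, edge);
  double R2 = radius * radius;
  long tries = 0, maxtries = 10000L * (long)std::max(1, n_spins);
  int got = 0;
  while (got < n_spins) {
    if (++tries > maxtries)
      stop("seed_spins: rejection sampling failed (extravascular volume ~ 0?)");
    double px = unif_rand() * edge, py = unif_rand() * edge,
           pz = unif_rand() * edge;
    if (!point_inside(ci, ax, ay, az, dx, dy, dz, R2, edge, px, py, pz)) {
      out(got, 0) = px; out(got, 1) = py; out(got, 2) = pz;
      ++got;
    }
  }
  return out;
}

// Random-walk phase accrual. Per interval j (duration dts[j] ms): phase
// increments with the field at the pre-step position (Euler), then an
// isotropic Gaussian step (per-axis sd sqrt(2 D dt)) is proposed; steps
// landing intravascularly are rejected (spin stays). Positions wrap
// periodically. Phases (rad) are recorded after intervals with rec = true.
// field_mode: 0 = trilinear on grid (gridvals, ngrid), 1 = exact superposition.
// [[Rcpp::export]]
List cpp_evolve_phases(NumericMatrix pos0, NumericMatrix axis,
                       NumericMatrix dir, double radius, double edge,
                       int field_mode, NumericVector gridvals,
                       int ngrid, double base, NumericVector dts,
                       LogicalVector rec, double D) {
  int nspin = pos0.nrow(), nint = dts.size(), ncyl = axis.nrow();
  int nrec = 0;
  for (int j = 0; j < nint; ++j) if (rec[j]) ++nrec;
  NumericMatrix phases(nspin, nrec);
  NumericMatrix disp(nspin, 3); // accumulated (unwrapped) accepted steps

  std::vector<double> ax, ay, az, dx, dy, dz;
  CellIndex ci;
  std::vector<CylField> cf;
  if (ncyl > 0) {
    mat_to_cols(axis, ax, ay, az);
    mat_to_cols(dir, dx, dy, dz);
    build_cell_index(ci, ax, ay, az, dx, dy, dz, radius, edge);
    if (field_mode == 1) precompute_field(cf, axis, dir, radius, base);
  }
  double R2 = radius * radius;
  double g = ngrid > 0 ? edge / ngrid : 1.0;

  std::vector<double> sds(nint);
  for (int j = 0; j < nint; ++j) sds[j] = std::sqrt(2.0 * D * dts[j]);

  for (int s = 0; s < nspin; ++s) {
    double px = wrap1(pos0(s, 0), edge), py = wrap1(pos0(s, 1), edge),
           pz = wrap1(pos0(s, 2), edge);
    double phi = 0.0;
    int r = 0;
    for (int j = 0; j < nint; ++j) {
      double w;
      if (ncyl == 0) {
        w = 0.0;
      } else if (field_mode == 0) {
        // inline trilinear
        double u = px / g, v = py / g, q = pz / g;
        int i0 = std::min(ngrid - 1, (int)u), j0 = std::min(ngrid - 1, (int)v),
            k0 = std::min(ngrid - 1, (int)q);
        double fu = u - i0, fv = v - j0, fw = q - k0;
        int i1 = (i0 + 1) % ngrid, j1 = (j0 + 1) % ngrid, k1 = (k0 + 1) % ngrid;
        double c00 = gridvals[((R_xlen_t)k0 * ngrid + j0) * ngrid + i0] * (1 - fu) +
                     gridvals[((R_xlen_t)k0 * ngrid + j0) * ngrid + i1] * fu;
        double c10 = gridvals[((R_xlen_t)k0 * ngrid + j1) * ngrid + i0] * (1 - fu) +
                     gridvals[((R_xlen_t)k0 * ngrid + j1) * ngrid + i1] * fu;
        double c01 = gridvals[((R_xlen_t)k1 * ngrid + j0) * ngrid + i0] * (1 - fu) +
                     gridvals[((R_xlen_t)k1 * ngrid + j0) * ngrid + i1] * fu;
        double c11 = gridvals[((R_xlen_t)k1 * ngrid + j1) * ngrid + i0] * (1 - fu) +
                     gridvals[((R_xlen_t)k1 * ngrid + j1) * ngrid + i1] * fu;
        w = (c00 * (1 - fv) + c10 * fv) * (1 - fw) +
            (c01 * (1 - fv) + c11 * fv) * fw;
      } else {
        double acc = 0.0;
        for (int c = 0; c < ncyl; ++c)
          for (int img = 0; img < 27; ++img) {
            int sx, sy, sz;
            img_shift(img, sx, sy, sz);
            acc += cyl_field_at(cf[c], R2, 1e60, px - sx * edge,
                                py - sy * edge, pz - sz * edge);
          }
        w = acc;
      }
      phi += w * dts[j] * 1e-3; // rad/s * ms -> rad
      if (D > 0.0) {
        double gx = norm_rand() * sds[j], gy = norm_rand() * sds[j],
               gz = norm_rand() * sds[j];
        double nx = wrap1(px + gx, edge);
        double ny = wrap1(py + gy, edge);
        double nz = wrap1(pz + gz, edge);
        if (ncyl == 0 ||
            !point_inside(ci, ax, ay, az, dx, dy, dz, R2, edge, nx, ny, nz)) {
          px = nx; py = ny; pz = nz;
          disp(s, 0) += gx; disp(s, 1) += gy; disp(s, 2) += gz;
        }
      }
      if (rec[j]) phases(s, r++) = phi;
    }
  }
  return List::create(_["phases"] = phases, _["displacement"] = disp);
}
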