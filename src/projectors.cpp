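#include "petchain_core.h"
using namespace Rcpp;

namespace {

struct VGrid {
  int nx, ny, nz;
  double vx, vy, vz, ox, oy, oz;
};

// Exact radiological path (Siddon): sum over traversed voxels of
// value * intersection length.  Positions in mm; with `mu` in cm^-1 the
// result (scaled by 0.1) is the dimensionless optical depth.
double siddon_one(const VGrid& g, const double* vol,
                  const double p0[3], const double p1[3]) {
  double d[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double L = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  if (L <= 0) return 0.0;
  double lo[3] = {g.ox, g.oy, g.oz};
  double hi[3] = {g.ox + g.nx * g.vx, g.oy + g.ny * g.vy, g.oz + g.nz * g.vz};
  double amin = 0.0, amax = 1.0;
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(d[k]) < 1e-12) {
      if (p0[k] <= lo[k] || p0[k] >= hi[k]) return 0.0;
    } else {
      double a = (lo[k] - p0[k]) / d[k], b = (hi[k] - p0[k]) / d[k];
      if (a > b) std::swap(a, b);
      amin = std::max(amin, a); amax = std::min(amax, b);
    }
  }
  if (amin >= amax) return 0.0;
  int dims[3] = {g.nx, g.ny, g.nz};
  double vox[3] = {g.vx, g.vy, g.vz};
  double eps = 1e-9;
  double a = amin + eps;
  int idx[3];
  double anext[3];
  int istep[3];
  for (int k = 0; k < 3; ++k) {
    double pk = p0[k] + a * d[k];
    idx[k] = (int)std::floor((pk - lo[k]) / vox[k]);
    if (idx[k] < 0) idx[k] = 0;
    if (idx[k] >= dims[k]) idx[k] = dims[k] - 1;
    if (d[k] > 1e-12) {
      istep[k] = 1;
      anext[k] = ((idx[k] + 1) * vox[k] + lo[k] - p0[k]) / d[k];
    } else if (d[k] < -1e-12) {
      istep[k] = -1;
      anext[k] = (idx[k] * vox[k] + lo[k] - p0[k]) / d[k];
    } else {
      istep[k] = 0;
      anext[k] = 2.0;
    }
  }
  double sum = 0.0;
  a = amin;
  while (a < amax - eps) {
    int kmin = 0;
    if (anext[1] < anext[kmin]) kmin = 1;
    if (anext[2] < anext[kmin]) kmin = 2;
    double anew = std::min(anext[kmin], amax);
    double seg = (anew - a) * L;
    if (seg > 0 && idx[0] >= 0 && idx[0] < g.nx && idx[1] >= 0 &&
        idx[1] < g.ny && idx[2] >= 0 && idx[2] < g.nz) {
      long v = (long)idx[0] + (long)g.nx * (idx[1] + (long)g.ny * idx[2]);
      sum += vol[v] * seg;
    }
    a = anew;
    if (anext[kmin] <= amax) {
      idx[kmin] += istep[kmin];
      anext[kmin] += vox[kmin] / std::fabs(d[kmin]);
      if (idx[kmin] < 0 || idx[kmin] >= dims[kmin]) break;
    }
  }
  return sum;
}

// Joseph projector: sampling at voxel-pitch steps along the dominant axis
// with bilinear interpolation in the two transverse axes.  fwd accumulates
// interp(img) * step; back spreads val * step with the same weights, making
// the pair an exact adjoint.
template <bool FWD>
double joseph_ray(const VGrid& g, double* vol, const double p0[3],
                  const double p1[3], double val) {
  double d[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double L = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  if (L <= 0) return 0.0;
  int dims[3] = {g.nx, g.ny, g.nz};
  double vox[3] = {g.vx, g.vy, g.vz};
  double lo[3] = {g.ox, g.oy, g.oz};
  int A = 0;  // dominant axis (largest |d| in voxel units)
  double best = 0.0;
  for (int k = 0; k < 3; ++k) {
    double r = std::fabs(d[k]) / vox[k];
    if (r > best) { best = r; A = k; }
  }
  int B = (A + 1) % 3, C = (A + 2) % 3;
  double step = vox[A] * L / std::fabs(d[A]);   // path length per plane
  double amin = 0.0, amax = 1.0;
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(d[k]) < 1e-12) {
      if (p0[k] <= lo[k] || p0[k] >= lo[k] + dims[k] * vox[k]) return 0.0;
    } else {
      double a = (lo[k] - p0[k]) / d[k], b = (lo[k] + dims[k] * vox[k] - p0[k]) / d[k];
      if (a > b) std::swap(a, b);
      amin = std::max(amin, a); amax = std::min(amax, b);
    }
  }
  if (amin >= amax) return 0.0;
  double c0 = p0[A] + amin * d[A], c1 = p0[A] + amax * d[A];
  if (c0 > c1) std::swap(c0, c1);
  int i0 = (int)std::ceil((c0 - lo[A]) / vox[A] - 0.5);
  int i1 = (int)std::floor((c1 - lo[A]) / vox[A] - 0.5);
  if (i0 < 0) i0 = 0;
  if (i1 >= dims[A]) i1 = dims[A] - 1;
  if (i1 < i0) return 0.0;
  long sA, sB, sC;
  {
    long strides[3] = {1, g.nx, (long)g.nx * g.ny};
    sA = strides[A]; sB = strides[B]; sC = strides[C];
  }
  // transverse coordinates are linear in the plane index
  double dt = vox[A] / d[A];
  double t0 = (lo[A] + (i0 + 0.5) * vox[A] - p0[A]) / d[A];
  double pb = (p0[B] + t0 * d[B] - lo[B]) / vox[B] - 0.5;
  double pc = (p0[C] + t0 * d[C] - lo[C]) / vox[C] - 0.5;
  double dpb = dt * d[B] / vox[B];
  double dpc = dt * d[C] / vox[C];
  double sum = 0.0;
  for (int i = i0; i <= i1; ++i, pb += dpb, pc += dpc) {
    int jb = (int)std::floor(pb), jc = (int)std::floor(pc);
    double fb = pb - jb, fc = pc - jc;
    if (jb >= 0 && jb < dims[B] - 1 && jc >= 0 && jc < dims[C] - 1) {
      long v = (long)i * sA + (long)jb * sB + (long)jc * sC;
      if (FWD) {
        sum += step * ((1.0 - fb) * ((1.0 - fc) * vol[v] + fc * vol[v + sC])
                       + fb * ((1.0 - fc) * vol[v + sB]
                               + fc * vol[v + sB + sC]));
      } else {
        double vs = val * step;
        vol[v] += vs * (1.0 - fb) * (1.0 - fc);
        vol[v + sC] += vs * (1.0 - fb) * fc;
        vol[v + sB] += vs * fb * (1.0 - fc);
        vol[v + sB + sC] += vs * fb * fc;
      }
    } else {
      // boundary: per-corner bounds checks
      for (int ob = 0; ob < 2; ++ob) {
        int b = jb + ob;
        if (b < 0 || b >= dims[B]) continue;
        double wb = ob ? fb : 1.0 - fb;
        for (int oc = 0; oc < 2; ++oc) {
          int cc = jc + oc;
          if (cc < 0 || cc >= dims[C]) continue;
          double w = wb * (oc ? fc : 1.0 - fc);
          long v = (long)i * sA + (long)b * sB + (long)cc * sC;
          if (FWD) sum += vol[v] * w * step;
          else vol[v] += val * w * step;
        }
      }
    }
  }
  return sum;
}

// TOF-weighted Joseph ray: each sample is weighted by the probability that
// the annihilation position falls inside the TOF bin [xi_lo, xi_hi] (mm
// along the ray, measured from the midpoint towards p1), under a Gaussian
// localisation kernel of width sigma_mm.
template <bool FWD>
double joseph_ray_tof(const VGrid& g, double* vol, const double p0[3],
                      const double p1[3], double val, double xi_lo,
                      double xi_hi, double sigma_mm) {
  double d[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
  double L = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  if (L <= 0) return 0.0;
  int dims[3] = {g.nx, g.ny, g.nz};
  double vox[3] = {g.vx, g.vy, g.vz};
  double lo[3] = {g.ox, g.oy, g.oz};
  int A = 0;
  double best = 0.0;
  for (int k = 0; k < 3; ++k) {
    double r = std::fabs(d[k]) / vox[k];
    if (r > best) { best = r; A = k; }
  }
  int B = (A + 1) % 3, C = (A + 2) % 3;
  double step = vox[A] * L / std::fabs(d[A]);
  double amin = 0.0, amax = 1.0;
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(d[k]) < 1e-12) {
      if (p0[k] <= lo[k] || p0[k] >= lo[k] + dims[k] * vox[k]) return 0.0;
    } else {
      double a = (lo[k] - p0[k]) / d[k], b = (lo[k] + dims[k] * vox[k] - p0[k]) / d[k];
      if (a > b) std::swap(a, b);
      amin = std::max(amin, a); amax = std::min(amax, b);
    }
  }
  // restrict to the TOF kernel support: xi = (t - 0.5) L
  double t_lo = 0.5 + (xi_lo - 4.0 * sigma_mm) / L;
  double t_hi = 0.5 + (xi_hi + 4.0 * sigma_mm) / L;
  amin = std::max(amin, std::min(t_lo, t_hi));
  amax = std::min(amax, std::max(t_lo, t_hi));
  if (amin >= amax) return 0.0;
  double c0 = p0[A] + amin * d[A], c1 = p0[A] + amax * d[A];
  if (c0 > c1) std::swap(c0, c1);
  int i0 = (int)std::ceil((c0 - lo[A]) / vox[A] - 0.5);
  int i1 = (int)std::floor((c1 - lo[A]) / vox[A] - 0.5);
  if (i0 < 0) i0 = 0;
  if (i1 >= dims[A]) i1 = dims[A] - 1;
  if (i1 < i0) return 0.0;
  long sA, sB, sC;
  {
    long strides[3] = {1, g.nx, (long)g.nx * g.ny};
    sA = strides[A]; sB = strides[B]; sC = strides[C];
  }
  // tabulated TOF-bin weight F(xi) = Phi((hi-xi)/s) - Phi((lo-xi)/s)
  static std::vector<double> lut;
  static double lut_lo = 0, lut_step = 0, lut_key_lo = 1e300,
                lut_key_hi = 1e300, lut_key_s = 0;
  if (xi_lo != lut_key_lo || xi_hi != lut_key_hi || sigma_mm != lut_key_s) {
    double inv_s = 1.0 / (sigma_mm * M_SQRT2);
    lut_lo = xi_lo - 4.5 * sigma_mm;
    double hi_end = xi_hi + 4.5 * sigma_mm;
    int nlut = (int)((hi_end - lut_lo)) + 2;   // ~1 mm resolution
    lut_step = (hi_end - lut_lo) / (nlut - 1);
    lut.resize(nlut);
    for (int k = 0; k < nlut; ++k) {
      double x = lut_lo + k * lut_step;
      lut[k] = 0.5 * (std::erf((xi_hi - x) * inv_s) -
                      std::erf((xi_lo - x) * inv_s));
    }
    lut_key_lo = xi_lo; lut_key_hi = xi_hi; lut_key_s = sigma_mm;
  }
  double inv_lstep = 1.0 / lut_step;
  int nlut1 = (int)lut.size() - 1;
  double dt = vox[A] / d[A];
  double t0 = (lo[A] + (i0 + 0.5) * vox[A] - p0[A]) / d[A];
  double pb = (p0[B] + t0 * d[B] - lo[B]) / vox[B] - 0.5;
  double pc = (p0[C] + t0 * d[C] - lo[C]) / vox[C] - 0.5;
  double dpb = dt * d[B] / vox[B];
  double dpc = dt * d[C] / vox[C];
  double uu = ((t0 - 0.5) * L - lut_lo) * inv_lstep;
  double duu = dt * L * inv_lstep;
  double sum = 0.0;
  for (int i = i0; i <= i1; ++i, pb += dpb, pc += dpc, uu += duu) {
    if (uu <= 0 || uu >= nlut1) continue;
    int ku = (int)uu;
    double w_tof = lut[ku] + (uu - ku) * (lut[ku + 1] - lut[ku]);
    if (w_tof <= 1e-9) continue;
    int jb = (int)std::floor(pb), jc = (int)std::floor(pc);
    double fb = pb - jb, fc = pc - jc;
    double ws = w_tof * step;
    if (jb >= 0 && jb < dims[B] - 1 && jc >= 0 && jc < dims[C] - 1) {
      long v = (long)i * sA + (long)jb * sB + (long)jc * sC;
      if (FWD) {
        sum += ws * ((1.0 - fb) * ((1.0 - fc) * vol[v] + fc * vol[v + sC])
                     + fb * ((1.0 - fc) * vol[v + sB]
                             + fc * vol[v + sB + sC]));
      } else {
        double vs = val * ws;
        vol[v] += vs * (1.0 - fb) * (1.0 - fc);
        vol[v + sC] += vs * (1.0 - fb) * fc;
        vol[v + sB] += vs * fb * (1.0 - fc);
        vol[v + sB + sC] += vs * fb * fc;
      }
    } else {
      for (int ob = 0; ob < 2; ++ob) {
        int b = jb + ob;
        if (b < 0 || b >= dims[B]) continue;
        double wb = ob ? fb : 1.0 - fb;
        for (int oc = 0; oc < 2; ++oc) {
          int cc = jc + oc;
          if (cc < 0 || cc >= dims[C]) continue;
          double w = wb * (oc ? fc : 1.0 - fc) * ws;
          long v = (long)i * sA + (long)b * sB + (long)cc * sC;
          if (FWD) sum += vol[v] * w;
          else vol[v] += val * w;
        }
      }
    }
  }
  return sum;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_siddon(NumericVector vol, IntegerVector dims,
                         NumericVector voxel, NumericVector origin,
                         NumericMatrix P0, NumericMatrix P1) {
  VGrid g{dims[0], dims[1], dims[2], voxel[0], voxel[1], voxel[2],
          origin[0], origin[1], origin[2]};
  int n = P0.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p0[3] = {P0(i, 0), P0(i, 1), P0(i, 2)};
    double p1[3] = {P1(i, 0), P1(i, 1), P1(i, 2)};
    out[i] = siddon_one(g, REAL(vol), p0, p1);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_joseph_fwd(NumericVector img, IntegerVector dims,
                             NumericVector voxel, NumericVector origin,
                             NumericMatrix P0, NumericMatrix P1) {
  VGrid g{dims[0], dims[1], dims[2], voxel[0], voxel[1], voxel[2],
          origin[0], origin[1], origin[2]};
  int n = P0.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p0[3] = {P0(i, 0), P0(i, 1), P0(i, 2)};
    double p1[3] = {P1(i, 0), P1(i, 1), P1(i, 2)};
    out[i] = joseph_ray<true>(g, REAL(img), p0, p1, 0.0);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_joseph_back(NumericVector vals, IntegerVector dims,
                              NumericVector voxel, NumericVector origin,
                              NumericMatrix P0, NumericMatrix P1) {
  VGrid g{dims[0], dims[1], dims[2], voxel[0], voxel[1], voxel[2],
          origin[0], origin[1], origin[2]};
  NumericVector img((R_xlen_t)dims[0] * dims[1] * dims[2]);
  int n = P0.nrow();
  for (int i = 0; i < n; ++i) {
    if (vals[i] == 0.0) continue;
    double p0[3] = {P0(i, 0), P0(i, 1), P0(i, 2)};
    double p1[3] = {P1(i, 0), P1(i, 1), P1(i, 2)};
    joseph_ray<false>(g, REAL(img), p0, p1, vals[i]);
  }
  return img;
}

// Pixel-driven 2-D backprojection of a ramp-filtered sinogram plane
// (radial x azimuthal), for the FBP initialiser.
// [[Rcpp::export]]
NumericVector cpp_backproject2d(NumericMatrix q, double rad_extent,
                                int nx, int ny, double vx, double vy,
                                double ox, double oy) {
  int n_rad = q.nrow(), n_az = q.ncol();
  NumericVector img((R_xlen_t)nx * ny);
  double dphi = M_PI / n_az;
  std::vector<double> sphi(n_az), cphi(n_az);
  for (int v = 0; v < n_az; ++v) {
    double phi = (v + 0.5) * dphi;
    sphi[v] = std::sin(phi); cphi[v] = std::cos(phi);
  }
  double ds = 2.0 * rad_extent / n_rad;
  for (int iy = 0; iy < ny; ++iy) {
    double y = oy + (iy + 0.5) * vy;
    for (int ix = 0; ix < nx; ++ix) {
      double x = ox + (ix + 0.5) * vx;
      double sum = 0.0;
      for (int v = 0; v < n_az; ++v) {
        double s = -x * sphi[v] + y * cphi[v];
        double u = (s + rad_extent) / ds - 0.5;
        int j = (int)std::floor(u);
        double f = u - j;
        if (j < 0 || j >= n_rad - 1) continue;
        sum += (1.0 - f) * q(j, v) + f * q(j + 1, v);
      }
      img[(R_xlen_t)ix + (R_xlen_t)nx * iy] = sum * dphi;
    }
  }
  return img;
}

// [[Rcpp::export]]
NumericVector cpp_joseph_fwd_tof(NumericVector img, IntegerVector dims,
                                 NumericVector voxel, NumericVector origin,
                                 NumericMatrix P0, NumericMatrix P1,
                                 double xi_lo, double xi_hi,
                                 double sigma_mm) {
  VGrid g{dims[0], dims[1], dims[2], voxel[0], voxel[1], voxel[2],
          origin[0], origin[1], origin[2]};
  int n = P0.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p0[3] = {P0(i, 0), P0(i, 1), P0(i, 2)};
    double p1[3] = {P1(i, 0), P1(i, 1), P1(i, 2)};
    out[i] = joseph_ray_tof<true>(g, REAL(img), p0, p1, 0.0, xi_lo, xi_hi,
                                  sigma_mm);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_joseph_back_tof(NumericVector vals, IntegerVector dims,
                                  NumericVector voxel, NumericVector origin,
                                  NumericMatrix P0, NumericMatrix P1,
                                  double xi_lo, double xi_hi,
                                  double sigma_mm, NumericVector img0) {
  VGrid g{dims[0], dims[1], dims[2], voxel[0], voxel[1], voxel[2],
          origin[0], origin[1], origin[2]};
  NumericVector img;
  if (img0.size() == (R_xlen_t)dims[0] * dims[1] * dims[2]) img = img0;
  else img = NumericVector((R_xlen_t)dims[0] * dims[1] * dims[2]);
  int n = P0.nrow();
  for (int i = 0; i < n; ++i) {
    if (vals[i] == 0.0) continue;
    double p0[3] = {P0(i, 0), P0(i, 1), P0(i, 2)};
    double p1[3] = {P1(i, 0), P1(i, 1), P1(i, 2)};
    joseph_ray_tof<false>(g, REAL(img), p0, p1, vals[i], xi_lo, xi_hi,
                          sigma_mm);
  }
  return img;
}
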