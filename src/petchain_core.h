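#ifndef PETCHAIN_CORE_H
#define PETCHAIN_CORE_H

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>

// xoshiro256++ (public-domain algorithm): fast 64-bit generator with a
// std::uniform-compatible interface, seeded through splitmix64.
struct XoshiroRng {
  uint64_t s[4];
  typedef uint64_t result_type;
  static constexpr uint64_t min() { return 0; }
  static constexpr uint64_t max() { return ~0ULL; }
  explicit XoshiroRng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t operator()() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
};

// ---- scanner geometry ------------------------------------------------------
// Cylindrical scanner: n_sector rsectors, n_tax_sector transaxial crystals per
// rsector (contiguous arc, gaps between rsectors), n_rings axial rings.
// rsector 0 centred at +y (12 o'clock seen from the front), indices increase
// clockwise seen from the front, i.e. towards +x.
struct Geom {
  int n_sector;        // 34
  int n_tax_sector;    // 16
  int n_rings;         // 36
  double R;            // front-face radius, mm (372.1)
  double sector_ang;   // 2*pi/n_sector
  double dalpha;       // angular crystal pitch within an rsector
  double zpitch;       // axial crystal pitch, mm
  int min_sector_diff; // 4
};

inline Geom geom_from_list(const Rcpp::List& g) {
  Geom G;
  G.n_sector = Rcpp::as<int>(g["n_sector"]);
  G.n_tax_sector = Rcpp::as<int>(g["n_tax_sector"]);
  G.n_rings = Rcpp::as<int>(g["n_rings"]);
  G.R = Rcpp::as<double>(g["radius"]);
  G.dalpha = Rcpp::as<double>(g["dalpha"]);
  G.zpitch = Rcpp::as<double>(g["zpitch"]);
  G.min_sector_diff = Rcpp::as<int>(g["min_sector_diff"]);
  G.sector_ang = 2.0 * M_PI / G.n_sector;
  return G;
}

// clockwise angle (from +y) of transaxial crystal t
inline double crystal_alpha(const Geom& G, int tax) {
  int sec = tax / G.n_tax_sector;
  int tin = tax % G.n_tax_sector;
  return sec * G.sector_ang + (tin - (G.n_tax_sector - 1) / 2.0) * G.dalpha;
}

inline void crystal_xy(const Geom& G, int tax, double& x, double& y) {
  double a = crystal_alpha(G, tax);
  // theta measured CCW from +x; alpha clockwise from +y => theta = pi/2 - alpha
  double th = M_PI / 2.0 - a;
  x = G.R * std::cos(th);
  y = G.R * std::sin(th);
}

inline double crystal_z(const Geom& G, int ring) {
  return (ring - (G.n_rings - 1) / 2.0) * G.zpitch;
}

inline int sector_diff(const Geom& G, int tax1, int tax2) {
  int s1 = tax1 / G.n_tax_sector, s2 = tax2 / G.n_tax_sector;
  int d = std::abs(s1 - s2);
  return std::min(d, G.n_sector - d);
}

// ---- sinogram layout -------------------------------------------------------
// mode 0: SSRB direct planes, plane = ring1 + ring2 (2*n_rings-1 planes)
// mode 1: span-1 Michelogram, plane = min(r)*n_rings + max(r)
struct Layout {
  int n_rad, n_az, n_planes, mode, tof_bins, max_ring_diff;
  double rad_extent;   // mm (350)
  double tof_width;    // ps
};

inline Layout layout_from_list(const Rcpp::List& l) {
  Layout L;
  L.n_rad = Rcpp::as<int>(l["n_radial"]);
  L.n_az = Rcpp::as<int>(l["n_azimuthal"]);
  L.n_planes = Rcpp::as<int>(l["n_planes"]);
  L.mode = Rcpp::as<int>(l["mode"]);
  L.tof_bins = Rcpp::as<int>(l["tof_bins"]);
  L.max_ring_diff = Rcpp::as<int>(l["max_ring_diff"]);
  L.rad_extent = Rcpp::as<double>(l["radial_extent"]);
  L.tof_width = Rcpp::as<double>(l["tof_width"]);
  return L;
}

// Returns 0-based linear bin index, or -1 when rejected.
// tof_delta (ps) is t1 - t2; the canonical crystal order (smaller ring, then
// smaller transaxial index first) defines the TOF sign, so swapping the two
// crystals yields the same non-TOF bin and a negated TOF offset.
inline long lor_bin(const Geom& G, const Layout& L,
                    int tax1, int ring1, int tax2, int ring2,
                    double tof_delta) {
  if (sector_diff(G, tax1, tax2) < G.min_sector_diff) return -1;
  if (std::abs(ring1 - ring2) > L.max_ring_diff) return -1;
  // canonical order
  if (ring2 < ring1 || (ring2 == ring1 && tax2 < tax1)) {
    std::swap(tax1, tax2); std::swap(ring1, ring2);
    tof_delta = -tof_delta;
  }
  double x1, y1, x2, y2;
  crystal_xy(G, tax1, x1, y1);
  crystal_xy(G, tax2, x2, y2);
  double dx = x2 - x1, dy = y2 - y1;
  double nrm = std::sqrt(dx * dx + dy * dy);
  if (nrm < 1e-9) return -1;
  double phi = std::atan2(dy, dx);
  if (phi < 0) phi += M_PI;
  if (phi >= M_PI) phi -= M_PI;
  double s = -x1 * std::sin(phi) + y1 * std::cos(phi);
  if (std::fabs(s) > L.rad_extent) return -1;
  int irad = (int)std::floor((s + L.rad_extent) / (2.0 * L.rad_extent) * L.n_rad);
  if (irad < 0) irad = 0;
  if (irad >= L.n_rad) irad = L.n_rad - 1;
  int iaz = (int)std::floor(phi / M_PI * L.n_az);
  if (iaz < 0) iaz = 0;
  if (iaz >= L.n_az) iaz = L.n_az - 1;
  int ipl;
  if (L.mode == 0) ipl = ring1 + ring2;
  else ipl = ring1 * G.n_rings + ring2;
  long idx = (long)irad + (long)L.n_rad * (iaz + (long)L.n_az * ipl);
  if (L.tof_bins > 1) {
    // geometric TOF sign: positive offsets point towards the bin-ray end
    // with the larger projection on the LOR direction (p1 side)
    double proj1 = x1 * std::cos(phi) + y1 * std::sin(phi);
    double proj2 = x2 * std::cos(phi) + y2 * std::sin(phi);
    if (proj1 > proj2) tof_delta = -tof_delta;
    int itof = (int)std::floor(tof_delta / L.tof_width + L.tof_bins / 2.0);
    if (itof < 0) itof = 0;
    if (itof >= L.tof_bins) itof = L.tof_bins - 1;
    idx += (long)L.n_rad * L.n_az * L.n_planes * itof;
  }
  return idx;
}

// fast uniform(0,1) from a 64-bit generator
template <class RNG>
inline double u01(RNG& rng) {
  return (((uint64_t)rng() >> 11) + 0.5) * 0x1.0p-53;
}

// ---- photon physics --------------------------------------------------------
const double ME_KEV = 511.0;

// total Klein-Nishina cross-section per electron, relative units
inline double sigma_kn(double E) {
  double a = E / ME_KEV;
  double l = std::log(1.0 + 2.0 * a);
  return (1.0 + a) / (a * a) * (2.0 * (1.0 + a) / (1.0 + 2.0 * a) - l / a)
       + l / (2.0 * a) - (1.0 + 3.0 * a) / ((1.0 + 2.0 * a) * (1.0 + 2.0 * a));
}

// energy scaling of water-like linear attenuation (Compton dominated; a small
// photoelectric term with ~E^-3 dependence)
const double FPE_WATER = 1.5e-4;
inline double mu_scale(double E) {
  double kkn = sigma_kn(E) / sigma_kn(ME_KEV);
  double r = ME_KEV / E;
  return (1.0 - FPE_WATER) * kkn + FPE_WATER * r * r * r;
}
inline double pe_share(double E) {
  double r = ME_KEV / E;
  double pe = FPE_WATER * r * r * r;
  return pe / ((1.0 - FPE_WATER) * sigma_kn(E) / sigma_kn(ME_KEV) + pe);
}

// LYSO linear attenuation (1/cm), log-log interpolated coarse table
inline double mu_lyso(double E) {
  static const double eg[7] = {100, 150, 200, 300, 400, 511, 650};
  static const double mg[7] = {7.8, 3.38, 1.85, 1.17, 0.95, 0.84, 0.76};
  if (E <= eg[0]) return mg[0];
  if (E >= eg[6]) return mg[6];
  int i = 0;
  while (E > eg[i + 1]) ++i;
  double t = (std::log(E) - std::log(eg[i])) / (std::log(eg[i + 1]) - std::log(eg[i]));
  return std::exp((1.0 - t) * std::log(mg[i]) + t * std::log(mg[i + 1]));
}

// differential KN cross-section (relative), x = cos(theta)
inline double kn_diff(double E, double x) {
  double a = E / ME_KEV;
  double f = 1.0 / (1.0 + a * (1.0 - x)); // E'/E
  return f * f * (f + 1.0 / f - (1.0 - x * x));
}

// rejection sampling of the Compton scattering angle
template <class RNG>
inline double sample_kn_costheta(double E, RNG& rng) {
  double fmax = kn_diff(E, 1.0);
  for (;;) {
    double x = 2.0 * u01(rng) - 1.0;
    if (u01(rng) * fmax <= kn_diff(E, x)) return x;
  }
}

#endif
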