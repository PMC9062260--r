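#include "petchain_core.h"
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  double vx, vy, vz;        // mm
  double ox, oy, oz;        // corner origin, mm
  const double* mu;         // cm^-1 at 511 keV
  double mumax;
};

inline bool voxel_of(const Grid& g, double x, double y, double z,
                     long& idx) {
  int ix = (int)std::floor((x - g.ox) / g.vx);
  int iy = (int)std::floor((y - g.oy) / g.vy);
  int iz = (int)std::floor((z - g.oz) / g.vz);
  if (ix < 0 || iy < 0 || iz < 0 || ix >= g.nx || iy >= g.ny || iz >= g.nz)
    return false;
  idx = (long)ix + (long)g.nx * (iy + (long)g.ny * iz);
  return true;
}

// parametric intersection of ray with grid bounding box
inline bool ray_box(const Grid& g, const double p[3], const double d[3],
                    double& t0, double& t1) {
  t0 = 0.0; t1 = 1e30;
  double lo[3] = {g.ox, g.oy, g.oz};
  double hi[3] = {g.ox + g.nx * g.vx, g.oy + g.ny * g.vy, g.oz + g.nz * g.vz};
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(d[k]) < 1e-12) {
      if (p[k] <= lo[k] || p[k] >= hi[k]) return false;
    } else {
      double a = (lo[k] - p[k]) / d[k], b = (hi[k] - p[k]) / d[k];
      if (a > b) std::swap(a, b);
      t0 = std::max(t0, a); t1 = std::min(t1, b);
    }
  }
  return t1 > t0;
}

template <class RNG>
inline void rotate_dir(double d[3], double cost, double psi) {
  // rotate d by polar angle acos(cost) about itself with azimuth psi
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  // orthonormal basis (u, v, d)
  double u[3], v[3];
  if (std::fabs(d[2]) < 0.9) { u[0] = -d[1]; u[1] = d[0]; u[2] = 0.0; }
  else { u[0] = 0.0; u[1] = -d[2]; u[2] = d[1]; }
  double nu = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
  for (int k = 0; k < 3; ++k) u[k] /= nu;
  v[0] = d[1]*u[2] - d[2]*u[1];
  v[1] = d[2]*u[0] - d[0]*u[2];
  v[2] = d[0]*u[1] - d[1]*u[0];
  double cp = std::cos(psi), sp = std::sin(psi);
  for (int k = 0; k < 3; ++k)
    d[k] = sint * (cp * u[k] + sp * v[k]) + cost * d[k];
}

// Woodcock (delta-tracking) transport through the voxel grid.
// Returns true if the photon survives (exits the grid), false if absorbed.
// Updates pos, dir, E, nscat and accumulates path length (mm).
template <class RNG>
bool track(const Grid& g, double pos[3], double dir[3], double& E,
           int& nscat, double& path, bool scatter_on, double kill_E,
           RNG& rng) {
  
  if (g.mumax <= 0.0) return true;
  for (;;) {
    double ks = mu_scale(E);
    double mu_major = g.mumax * ks;           // cm^-1
    double t0, t1;
    if (!ray_box(g, pos, dir, t0, t1)) return true;   // misses / leaves grid
    double t = (t0 > 0.0) ? t0 : 0.0;
    for (;;) {
      t += -std::log(u01(rng)) / (mu_major * 0.1);      // step in mm
      if (t >= t1) {  // left the grid
        for (int k = 0; k < 3; ++k) pos[k] += dir[k] * t1;
        path += t1;
        return true;
      }
      double q[3] = {pos[0] + dir[0] * t, pos[1] + dir[1] * t,
                     pos[2] + dir[2] * t};
      long idx;
      double mu_here = 0.0;
      if (voxel_of(g, q[0], q[1], q[2], idx)) mu_here = g.mu[idx] * ks;
      if (u01(rng) * mu_major < mu_here) {
        // real interaction
        for (int k = 0; k < 3; ++k) pos[k] = q[k];
        path += t;
        if (!scatter_on) return false;
        if (u01(rng) < pe_share(E)) return false;       // photoelectric
        double cost = sample_kn_costheta(E, rng);
        rotate_dir<RNG>(dir, cost, 2.0 * M_PI * u01(rng));
        E = E / (1.0 + (E / ME_KEV) * (1.0 - cost));
        ++nscat;
        if (E < kill_E) return false;
        break;  // restart with new majorant for the new energy
      }
    }
  }
}

// Project the photon to the detector ring.  The bore liner attenuates
// (interacting photons are discarded; liner scatter is not modelled).
// Returns true when a crystal is hit (and, optionally, stops the photon
// with the LYSO interaction probability).
template <class RNG>
bool detect(const Geom& G, const double pos0[3], const double dir0[3],
            double& E, double liner_r, double liner_t, double liner_mu,
            bool stopping, bool allow_scatter, double& flight, int& tax,
            int& ring, int& nscat, RNG& rng) {
  
  double p[3] = {pos0[0], pos0[1], pos0[2]};
  double d[3] = {dir0[0], dir0[1], dir0[2]};
  double travelled = 0.0;
  for (int pass = 0; pass < 2; ++pass) {
    double a = d[0] * d[0] + d[1] * d[1];
    if (a < 1e-12) return false;
    double b = 2.0 * (p[0] * d[0] + p[1] * d[1]);
    double c0 = p[0] * p[0] + p[1] * p[1];
    auto hit_t = [&](double R) -> double {
      double c = c0 - R * R;
      double disc = b * b - 4.0 * a * c;
      if (disc < 0) return -1.0;
      return (-b + std::sqrt(disc)) / (2.0 * a);
    };
    double tR = hit_t(G.R);
    if (tR <= 0) return false;
    if (pass == 0 && liner_mu > 0 && c0 < liner_r * liner_r) {
      double tin = hit_t(liner_r), tout = hit_t(liner_r + liner_t);
      if (tin > 0 && tout > tin) {
        double len = tout - tin;   // mm (direction normalised)
        if (u01(rng) >= std::exp(-liner_mu * mu_scale(E) * len / 10.0))
          return false;
      }
    }
    double z = p[2] + d[2] * tR;
    double v = z / G.zpitch + G.n_rings / 2.0;
    if (v < 0 || v >= G.n_rings) return false;
    double x = p[0] + d[0] * tR, y = p[1] + d[1] * tR;
    double al = M_PI / 2.0 - std::atan2(y, x);
    al -= 2.0 * M_PI * std::floor(al / (2.0 * M_PI));
    int sec = (int)std::floor(al / G.sector_ang + 0.5);
    double local = al - sec * G.sector_ang;
    sec %= G.n_sector;
    double u = local / G.dalpha + G.n_tax_sector / 2.0;
    if (u < 0 || u >= G.n_tax_sector) return false;   // inter-sector gap
    if (stopping && u01(rng) >= 1.0 - std::exp(-mu_lyso(E) * 2.5)) return false;
    tax = sec * G.n_tax_sector + (int)std::floor(u);
    ring = (int)std::floor(v);
    flight = travelled + tR;
    return true;
  }
  return false;
}

} // namespace

// Low-level transport of individual photons, for physics tests.
// [[Rcpp::export]]
List cpp_transport_photons(NumericMatrix pos, NumericMatrix dir,
                           NumericVector energy, NumericVector mu,
                           IntegerVector dims, NumericVector voxel,
                           NumericVector origin, bool scatter_on,
                           double kill_E, double seed) {
  Grid g{dims[0], dims[1], dims[2], voxel[0], voxel[1], voxel[2],
         origin[0], origin[1], origin[2], REAL(mu), 0.0};
  for (R_xlen_t i = 0; i < mu.size(); ++i) g.mumax = std::max(g.mumax, mu[i]);
  XoshiroRng rng((uint64_t)seed);
  int n = pos.nrow();
  NumericMatrix out_pos(n, 3), out_dir(n, 3);
  NumericVector out_E(n), out_path(n);
  IntegerVector out_nscat(n), out_alive(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double d[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};
    double nn = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    if (!R_finite(nn) || nn <= 0) stop("non-finite photon direction");
    for (int k = 0; k < 3; ++k) d[k] /= nn;
    double E = energy[i], path = 0.0;
    int ns = 0;
    bool alive = track(g, p, d, E, ns, path, scatter_on, kill_E, rng);
    for (int k = 0; k < 3; ++k) { out_pos(i, k) = p[k]; out_dir(i, k) = d[k]; }
    out_E[i] = E; out_nscat[i] = ns; out_alive[i] = alive ? 1 : 0;
    out_path[i] = path;
  }
  return List::create(_["pos"] = out_pos, _["dir"] = out_dir,
                      _["energy"] = out_E, _["n_scatters"] = out_nscat,
                      _["alive"] = out_alive, _["path_mm"] = out_path);
}

// [[Rcpp::export]]
NumericVector cpp_sample_kn(int n, double energy, double seed) {
  XoshiroRng rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sample_kn_costheta(energy, rng);
  return out;
}

namespace {
// Walker alias table for O(1) sampling of the emission voxel
struct AliasTable {
  std::vector<double> prob;
  std::vector<long> alias;
  void build(const double* w, long n) {
    prob.resize(n); alias.resize(n);
    double tot = 0;
    for (long i = 0; i < n; ++i) tot += w[i];
    std::vector<double> p(n);
    std::vector<long> small, large;
    for (long i = 0; i < n; ++i) {
      p[i] = w[i] * n / tot;
      (p[i] < 1.0 ? small : large).push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      long s = small.back(); small.pop_back();
      long l = large.back(); large.pop_back();
      prob[s] = p[s]; alias[s] = l;
      p[l] = (p[l] + p[s]) - 1.0;
      (p[l] < 1.0 ? small : large).push_back(l);
    }
    while (!large.empty()) { prob[large.back()] = 1.0; alias[large.back()] = large.back(); large.pop_back(); }
    while (!small.empty()) { prob[small.back()] = 1.0; alias[small.back()] = small.back(); small.pop_back(); }
  }
  template <class RNG>
  long draw(RNG& rng) const {
    double u = u01(rng) * prob.size();
    long i = (long)u;
    if (i >= (long)prob.size()) i = prob.size() - 1;
    return (u - i) < prob[i] ? i : alias[i];
  }
};
}

// Fused decay -> transport -> detection -> digitizer chain for one batch of
// annihilation decays.  Returns the post-window singles.
// [[Rcpp::export]]
List cpp_simulate_batch(double n_decays, NumericVector act_prob,
                        IntegerVector act_dims, NumericVector act_voxel,
                        NumericVector act_origin,
                        NumericVector mu, IntegerVector dims,
                        NumericVector voxel, NumericVector origin,
                        List geom, List par, double seed,
                        double id_offset) {
  Grid g{dims[0], dims[1], dims[2], voxel[0], voxel[1], voxel[2],
         origin[0], origin[1], origin[2], REAL(mu), 0.0};
  for (R_xlen_t i = 0; i < mu.size(); ++i) g.mumax = std::max(g.mumax, mu[i]);
  Geom G = geom_from_list(geom);
  double duration = as<double>(par["duration"]);         // s
  double eres = as<double>(par["energy_resolution_fwhm"]);
  double elo = as<double>(par["energy_window_lo"]);
  double ehi = as<double>(par["energy_window_hi"]);
  double tfwhm = as<double>(par["temporal_fwhm_ps"]);
  double det_eff = as<double>(par["detection_efficiency"]);
  bool scatter_on = as<bool>(par["scatter_on"]);
  double kill_E = as<double>(par["kill_energy"]);
  double liner_r = as<double>(par["liner_radius"]);
  double liner_t = as<double>(par["liner_thickness"]);
  double liner_mu = as<double>(par["liner_mu"]);
  bool stopping = as<bool>(par["crystal_stopping"]);
  double acol = as<double>(par["acollinearity_fwhm_deg"]);
  NumericVector crystal_eff;  // optional per-crystal efficiency (tax fastest)
  bool have_eff = par.containsElementNamed("crystal_eff");
  if (have_eff) {
    crystal_eff = as<NumericVector>(par["crystal_eff"]);
    have_eff = crystal_eff.size() > 0;
  }
  int n_tax_total = G.n_sector * G.n_tax_sector;
  XoshiroRng rng((uint64_t)seed);
  
  std::normal_distribution<double> N(0.0, 1.0);
  const double C_MM_NS = 299.792458;
  long n = (long)n_decays;
  std::vector<double> s_time, s_energy, s_id;
  std::vector<int> s_tax, s_ring, s_nscat;
  s_time.reserve(n / 2); // rough
  AliasTable at;
  at.build(REAL(act_prob), act_prob.size());
  for (long i = 0; i < n; ++i) {
    // emission position: voxel ~ activity, uniform jitter inside
    long lo = at.draw(rng);
    long iz = lo / ((long)act_dims[0] * act_dims[1]);
    long iy = (lo / act_dims[0]) % act_dims[1];
    long ix = lo % act_dims[0];
    double p0[3] = {act_origin[0] + (ix + u01(rng)) * act_voxel[0],
                    act_origin[1] + (iy + u01(rng)) * act_voxel[1],
                    act_origin[2] + (iz + u01(rng)) * act_voxel[2]};
    double ct = 2.0 * u01(rng) - 1.0, st = std::sqrt(1.0 - ct * ct);
    double ph = 2.0 * M_PI * u01(rng);
    double d1[3] = {st * std::cos(ph), st * std::sin(ph), ct};
    double d2[3] = {-d1[0], -d1[1], -d1[2]};
    if (acol > 0) {
      double dev = std::fabs(N(rng)) * (acol * M_PI / 180.0) / 2.3548;
      rotate_dir<XoshiroRng>(d2, std::cos(dev), 2.0 * M_PI * u01(rng));
    }
    double t0_ns = u01(rng) * duration * 1e9;
    // transport + detect both photons
    int htax[2], hring[2]; double hE[2], ht[2]; int hns[2]; bool hok[2];
    double* dd[2] = {d1, d2};
    for (int k = 0; k < 2; ++k) {
      double p[3] = {p0[0], p0[1], p0[2]};
      double E = ME_KEV, path = 0.0; int ns = 0;
      hok[k] = false;
      if (!track(g, p, dd[k], E, ns, path, scatter_on, kill_E, rng)) continue;
      double flight; int tax, ring;
      if (!detect(G, p, dd[k], E, liner_r, liner_t, liner_mu, stopping,
                  scatter_on, flight, tax, ring, ns, rng)) continue;
      hok[k] = true; htax[k] = tax; hring[k] = ring; hE[k] = E;
      ht[k] = t0_ns + (path + flight) / C_MM_NS; hns[k] = ns;
    }
    // rsector-level adder + energy-winner readout
    int nh = (hok[0] ? 1 : 0) + (hok[1] ? 1 : 0);
    if (nh == 0) continue;
    if (nh == 2 && htax[0] / G.n_tax_sector == htax[1] / G.n_tax_sector) {
      int w = (hE[0] >= hE[1]) ? 0 : 1;
      hE[w] += hE[1 - w];
      hns[w] = std::max(hns[0], hns[1]);
      hok[1 - w] = false;
    }
    for (int k = 0; k < 2; ++k) {
      if (!hok[k]) continue;
      double eff = det_eff;
      if (have_eff) eff *= crystal_eff[htax[k] + (long)n_tax_total * hring[k]];
      if (u01(rng) >= eff) continue;
      double sig = eres * std::sqrt(ME_KEV * hE[k]) / 2.3548;
      double Eb = hE[k] + sig * N(rng);
      if (Eb < elo || Eb > ehi) continue;
      double tb = ht[k] + (tfwhm / 2.3548) * N(rng) / 1000.0;  // ns
      s_time.push_back(tb);
      s_tax.push_back(htax[k]);
      s_ring.push_back(hring[k]);
      s_energy.push_back(Eb);
      s_nscat.push_back(hns[k]);
      s_id.push_back(id_offset + (double)i);
    }
  }
  return List::create(_["time_ns"] = wrap(s_time), _["tax"] = wrap(s_tax),
                      _["ring"] = wrap(s_ring), _["energy"] = wrap(s_energy),
                      _["n_scatters"] = wrap(s_nscat),
                      _["decay_id"] = wrap(s_id));
}
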