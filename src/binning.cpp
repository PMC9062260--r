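#include "petchain_core.h"
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_lor_bin(IntegerVector tax1, IntegerVector ring1,
                          IntegerVector tax2, IntegerVector ring2,
                          NumericVector tof_delta,
                          List geom, List layout) {
  Geom G = geom_from_list(geom);
  Layout L = layout_from_list(layout);
  R_xlen_t n = tax1.size();
  IntegerVector out(n);
  bool has_tof = tof_delta.size() == n;
  for (R_xlen_t i = 0; i < n; ++i) {
    long b = lor_bin(G, L, tax1[i], ring1[i], tax2[i], ring2[i],
                     has_tof ? tof_delta[i] : 0.0);
    out[i] = (b < 0) ? NA_INTEGER : (int)b;
  }
  return out;
}

// Histogram a coincidence list into a sinogram vector (length = prod of
// layout dims). Returns list(sino, n_accepted, n_rejected); with
// `integer_counts` the histogram is an integer vector (half the memory).
// [[Rcpp::export]]
List cpp_bin_events(IntegerVector tax1, IntegerVector ring1,
                    IntegerVector tax2, IntegerVector ring2,
                    NumericVector tof_delta, List geom, List layout,
                    bool integer_counts = false) {
  Geom G = geom_from_list(geom);
  Layout L = layout_from_list(layout);
  long nbin = (long)L.n_rad * L.n_az * L.n_planes * std::max(1, L.tof_bins);
  NumericVector sino(integer_counts ? 0 : nbin);
  IntegerVector sino_i(integer_counts ? nbin : 0);
  R_xlen_t n = tax1.size();
  bool has_tof = tof_delta.size() == n;
  long acc = 0, rej = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    long b = lor_bin(G, L, tax1[i], ring1[i], tax2[i], ring2[i],
                     has_tof ? tof_delta[i] : 0.0);
    if (b < 0) { ++rej; continue; }
    if (integer_counts) sino_i[b] += 1; else sino[b] += 1.0;
    ++acc;
  }
  return List::create(
      _["sino"] = integer_counts ? (SEXP)sino_i : (SEXP)sino,
      _["n_accepted"] = (double)acc, _["n_rejected"] = (double)rej);
}

// Enumerate every valid crystal pair once and accumulate, per non-TOF bin,
// the pair count and the sum of eps_1*eps_2*b_ring1*b_ring2.  Used to
// assemble the crystal-dependent part of the normalisation sinogram.
// `profile` (optional, values on a uniform grid over the radial extent)
// additionally accumulates sum eps*eps*b*b*profile(s_pair), evaluated at
// each pair's own closest-approach distance -- the exact per-bin
// expectation for a radially-profiled source, free of bin-centre bias.
// [[Rcpp::export]]
List cpp_enum_eta(NumericVector eps, NumericVector b_axial,
                  List geom, List layout,
                  NumericVector profile = NumericVector::create()) {
  Geom G = geom_from_list(geom);
  Layout L = layout_from_list(layout);
  int n_tax = G.n_sector * G.n_tax_sector;
  long nbin = (long)L.n_rad * L.n_az * L.n_planes;
  bool has_prof = profile.size() > 1;
  NumericVector npair(nbin), sum_eb(nbin),
      sum_ebp(has_prof ? nbin : 0);
  // precompute the (rad, az) bin and profile value per transaxial pair
  std::vector<long> txbin((size_t)n_tax * n_tax, -1);
  std::vector<double> txprof((size_t)n_tax * n_tax, 0.0);
  int np = profile.size();
  for (int t1 = 0; t1 < n_tax; ++t1) {
    double x1, y1; crystal_xy(G, t1, x1, y1);
    for (int t2 = t1; t2 < n_tax; ++t2) {
      if (sector_diff(G, t1, t2) < G.min_sector_diff) continue;
      double x2, y2; crystal_xy(G, t2, x2, y2);
      double dx = x2 - x1, dy = y2 - y1;
      double phi = std::atan2(dy, dx);
      if (phi < 0) phi += M_PI;
      if (phi >= M_PI) phi -= M_PI;
      double s = -x1 * std::sin(phi) + y1 * std::cos(phi);
      if (std::fabs(s) > L.rad_extent) continue;
      int irad = (int)std::floor((s + L.rad_extent) / (2.0 * L.rad_extent) * L.n_rad);
      if (irad < 0) irad = 0;
      if (irad >= L.n_rad) irad = L.n_rad - 1;
      int iaz = (int)std::floor(phi / M_PI * L.n_az);
      if (iaz >= L.n_az) iaz = L.n_az - 1;
      size_t key = (size_t)t1 * n_tax + t2;
      txbin[key] = (long)irad + (long)L.n_rad * iaz;
      if (has_prof) {
        double u = (s + L.rad_extent) / (2.0 * L.rad_extent) * (np - 1);
        int ku = (int)u;
        if (ku < 0) ku = 0;
        if (ku >= np - 1) ku = np - 2;
        txprof[key] = profile[ku] + (u - ku) * (profile[ku + 1] - profile[ku]);
      }
    }
  }
  int nr = G.n_rings;
  for (int t1 = 0; t1 < n_tax; ++t1) {
    for (int t2 = t1; t2 < n_tax; ++t2) {
      size_t key = (size_t)t1 * n_tax + t2;
      long tb = txbin[key];
      if (tb < 0) continue;
      double pv = txprof[key];
      for (int r1 = 0; r1 < nr; ++r1) {
        int r2start = (t1 == t2) ? r1 + 1 : 0;
        for (int r2 = r2start; r2 < nr; ++r2) {
          if (std::abs(r1 - r2) > L.max_ring_diff) continue;
          int ipl = (L.mode == 0) ? (r1 + r2)
                                  : (std::min(r1, r2) * nr + std::max(r1, r2));
          long bin = tb + (long)L.n_rad * L.n_az * ipl;
          double w = eps[(size_t)r1 * n_tax + t1] * eps[(size_t)r2 * n_tax + t2]
                   * b_axial[r1] * b_axial[r2];
          npair[bin] += 1.0;
          sum_eb[bin] += w;
          if (has_prof) sum_ebp[bin] += w * pv;
        }
      }
    }
  }
  return List::create(_["n_pairs"] = npair, _["sum_eb"] = sum_eb,
                      _["sum_ebp"] = sum_ebp);
}
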