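#include "petchain_core.h"
using namespace Rcpp;

// Multi-window coincidence sorter with takeAllGoods: every pair of singles
// whose time difference is within tau (i.e. inside the total 2*tau window)
// and whose rsector separation is >= the minimum sector difference becomes a
// prompt.  Input singles must be time-ordered.
// labels: 1 = true, 2 = scattered, 3 = random
// [[Rcpp::export]]
List cpp_sort_coincidences(NumericVector time_ns, IntegerVector tax,
                           IntegerVector ring, NumericVector decay_id,
                           IntegerVector nscat, double tau_ns, List geom) {
  Geom G = geom_from_list(geom);
  R_xlen_t n = time_ns.size();
  std::vector<int> out_i, out_j, out_label;
  std::vector<double> out_tof;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (i > 0 && time_ns[i] < time_ns[i - 1]) stop("singles not time-ordered");
    for (R_xlen_t j = i + 1; j < n && time_ns[j] - time_ns[i] <= tau_ns; ++j) {
      if (sector_diff(G, tax[i], tax[j]) < G.min_sector_diff) continue;
      int label;
      if (decay_id[i] >= 0 && decay_id[i] == decay_id[j])
        label = (nscat[i] + nscat[j] > 0) ? 2 : 1;
      else
        label = 3;
      out_i.push_back((int)(i + 1));
      out_j.push_back((int)(j + 1));
      out_label.push_back(label);
      out_tof.push_back((time_ns[i] - time_ns[j]) * 1000.0);  // ps
    }
  }
  return List::create(_["i"] = wrap(out_i), _["j"] = wrap(out_j),
                      _["label"] = wrap(out_label),
                      _["tof_delta_ps"] = wrap(out_tof));
}
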