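#' Sufficient statistics of a normalisation-calibration acquisition
#'
#' Reduces an acquisition to the binned sinogram and the per-crystal fan
#' counts, so calibration runs can be accumulated chunk-wise without
#' retaining event lists.
#' @keywords internal
norm_summary <- function(acq, layout, scanner) {
  ev <- if (inherits(acq, "petchain_acquisition")) acq$events else acq
  if (is.null(ev) || nrow(ev) == 0) stop("empty calibration acquisition")
  nb <- bin_events(ev, layout, scanner)
  n_tax <- scanner$spec$n_tax; n_rings <- scanner$spec$n_rings
  fan <- tabulate(ev$tax1 + n_tax * ev$ring1 + 1L, n_tax * n_rings) +
         tabulate(ev$tax2 + n_tax * ev$ring2 + 1L, n_tax * n_rings)
  list(bins = nb$array, fan = matrix(fan, n_tax, n_rings),
       n_events = nrow(ev))
}

add_norm_summary <- function(a, b) {
  if (is.null(a)) return(b)
  list(bins = a$bins + b$bins, fan = a$fan + b$fan,
       n_events = a$n_events + b$n_events)
}

#' Simulate the two normalisation-calibration acquisitions
#'
#' A uniform non-attenuating cylinder source (radius 100 mm) centred in
#' the scanner provides the axial factors and the intrinsic crystal
#' efficiencies; a thin annulus shell source (radius 355 mm, outside the
#' transaxial FOV) provides the transaxial (radial/interference) factors.
#' Both are reduced to accumulated sufficient statistics.
#'
#' @param scanner,cfg,layout Models and configuration.
#' @param n_decays_central,n_decays_annulus Total decays per source.
#' @param n_chunks Acquisition is split into this many sub-runs to bound
#'   memory.
#' @param seed RNG seed.
#' @param crystal_eff Optional per-crystal efficiency matrix applied in
#'   the simulation (for recovery experiments).
#' @return List with `central` and `annulus` summaries.
#' @export
normalisation_acquisitions <- function(scanner, cfg, layout,
                                       n_decays_central = 2e8,
                                       n_decays_annulus = 2e8,
                                       n_chunks = 10, seed = 1,
                                       crystal_eff = NULL) {
  zlen <- scanner$spec$n_rings * scanner$geom$zpitch
  run <- function(kind, radius, n_decays, seed0) {
    conc <- 1  # arbitrary: decays set through duration below
    ph <- build_phantom(phantom_spec(kind, background_concentration = conc,
                                     radius = radius, length = zlen),
                        voxel = 2)
    # duration such that activity x yield x duration = n_decays / n_chunks
    dur <- (n_decays / n_chunks) /
      (ph$total_activity_kBq * 1e3 * cfg$positron_yield)
    acc <- NULL
    for (k in seq_len(n_chunks)) {
      acq <- simulate_acquisition(ph, cfg, scanner, duration = dur,
                                  seed = seed0 + 13 * k,
                                  include_lu176 = FALSE, liner = FALSE,
                                  crystal_eff = crystal_eff,
                                  minimal_events = TRUE)
      acc <- add_norm_summary(acc, norm_summary(acq, layout, scanner))
      rm(acq); gc(verbose = FALSE)
    }
    acc
  }
  list(central = run("cylinder_source", 100, n_decays_central, seed),
       annulus = run("annulus_source", 355, n_decays_annulus, seed + 5000))
}

#' Component-based normalisation estimation
#'
#' Factorises the detector-pair sensitivity into: intrinsic crystal
#' efficiencies (fan-sums over the central-cylinder data, normalised per
#' ring), an axial block profile `b` (per-ring counts relative to their
#' smoothed profile), an axial geometric factor `g` (per-plane ratio of
#' observed to model-expected counts), and -- from the annulus data after
#' crystal/axial correction -- a radial profile `r` and a crystal
#' interference factor `f` (view phase within the rsector period x radial
#' bin).  The per-bin normalisation `eta` is the product of the
#' pair-aggregated crystal term (sum over the bin's crystal pairs of
#' `eps1 eps2 b1 b2`, which also carries the geometric pair-multiplicity
#' of the binning) with `g`, `r` and `f`, normalised to mean 1 over the
#' addressable bins.
#'
#' @param central,annulus Calibration data: acquisitions, event data
#'   frames, or summaries from [normalisation_acquisitions()].
#' @param scanner,layout Scanner model and layout.
#' @param central_radius,annulus_radius Source radii, mm.
#' @param smooth_window Running-mean window of the ring profile (rings).
#' @return An object of class `petchain_norm` with the component set and
#'   the assembled `eta` array.
#' @export
estimate_normalisation <- function(central, annulus, scanner, layout,
                                   central_radius = 100,
                                   annulus_radius = 355,
                                   smooth_window = 5) {
  as_sum <- function(x) {
    if (!is.null(x$bins)) x else norm_summary(x, layout, scanner)
  }
  cen <- as_sum(central); ann <- as_sum(annulus)
  if (cen$n_events == 0 || ann$n_events == 0)
    stop("empty calibration acquisition")
  n_tax <- scanner$spec$n_tax; n_rings <- scanner$spec$n_rings
  nr <- layout$n_radial; na <- layout$n_azimuthal; np <- layout$n_planes
  # crystal efficiencies: fan counts with the sector-averaged geometric
  # fan profile (per within-rsector position and ring) divided out, then
  # normalised within each ring
  fan <- cen$fan
  n_tax_sector <- scanner$geom$n_tax_sector
  pos <- (seq_len(n_tax) - 1) %% n_tax_sector
  pattern <- matrix(0, n_tax_sector, n_rings)
  for (pp in 0:(n_tax_sector - 1))
    pattern[pp + 1, ] <- colMeans(fan[pos == pp, , drop = FALSE])
  eps <- fan / pmax(pattern[pos + 1, ], 1e-12)
  eps <- sweep(eps, 2, pmax(colMeans(eps), 1e-12), "/")
  # axial block profile: ring totals relative to their smoothed profile
  ring_counts <- colSums(fan)
  pad <- (smooth_window - 1) / 2
  padded <- c(rep(ring_counts[1], pad), ring_counts,
              rep(ring_counts[n_rings], pad))
  smoothed <- stats::filter(padded, rep(1 / smooth_window, smooth_window))
  smoothed <- as.numeric(smoothed)[pad + seq_len(n_rings)]
  b <- ring_counts / pmax(smoothed, 1e-12)
  b <- b / mean(b)
  # pair-aggregated crystal terms with the source profiles evaluated at
  # each pair's own radial offset (bin-centre evaluation biases the steep
  # annulus profile near the field-of-view edge)
  ext <- layout$radial_extent
  prof_s <- seq(-ext, ext, length.out = 1401)
  chord_prof <- ifelse(abs(prof_s) < central_radius,
                       2 * sqrt(pmax(central_radius^2 - prof_s^2, 0)), 0)
  ann_prof <- ifelse(abs(prof_s) < annulus_radius,
                     1 / sqrt(pmax(1 - (prof_s / annulus_radius)^2, 1e-6)), 0)
  agg <- cpp_enum_eta(as.numeric(eps), b, scanner$geom, unclass(layout),
                      chord_prof)
  agg2 <- cpp_enum_eta(as.numeric(eps), b, scanner$geom, unclass(layout),
                       ann_prof)
  n_pairs <- array(agg$n_pairs, c(nr, na, np))
  sum_eb <- array(agg$sum_eb, c(nr, na, np))
  support <- n_pairs > 0
  expected_cyl <- array(agg$sum_ebp, c(nr, na, np))
  # axial geometric factor: per-plane observed / expected
  obs_p <- apply(cen$bins, 3, sum)
  exp_p <- apply(expected_cyl, 3, sum)
  g <- ifelse(exp_p > 0, obs_p / exp_p, 0)
  pos <- g > 0
  g[pos] <- g[pos] / stats::weighted.mean(g[pos], exp_p[pos])
  # annulus: radial and interference factors after eps/b/g correction
  expected_ann <- array(agg2$sum_ebp, c(nr, na, np)) *
    rep(g, each = nr * na)
  obs_r <- rowSums(ann$bins, dims = 1)
  exp_r <- rowSums(expected_ann, dims = 1)
  r_rad <- ifelse(exp_r > 0, obs_r / exp_r, 0)
  posr <- r_rad > 0
  r_rad[posr] <- r_rad[posr] / stats::weighted.mean(r_rad[posr], exp_r[posr])
  # view phase within one rsector period
  period <- as.integer(round(na / scanner$spec$n_rsector))
  vp <- (seq_len(na) - 1) %% period
  f <- matrix(1, period, nr)
  exp_rf <- expected_ann * rep(r_rad, na * np)
  for (p0 in 0:(period - 1)) {
    sel <- which(vp == p0)
    o <- rowSums(ann$bins[, sel, , drop = FALSE], dims = 1)
    e <- rowSums(exp_rf[, sel, , drop = FALSE], dims = 1)
    f[p0 + 1, ] <- ifelse(e > 0, o / e, 1)
  }
  f[!is.finite(f)] <- 1
  f <- f / mean(f[f > 0])
  # assemble eta
  f_arr <- array(t(f[vp + 1, , drop = FALSE]), c(nr, na, np))
  eta <- sum_eb * rep(g, each = nr * na) * array(r_rad, c(nr, na, np)) * f_arr
  m <- mean(eta[support & eta > 0])
  crystal_pair <- sum_eb / m
  eta <- eta / m
  structure(list(epsilon = eps, b_axial = b, g_axial = g, r_radial = r_rad,
                 f_interference = f, crystal_pair = crystal_pair,
                 n_pairs = n_pairs, eta = eta, support = support,
                 interference_period = period),
            class = "petchain_norm")
}
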