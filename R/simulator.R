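#' Digitizer / acquisition configuration
#'
#' Parameters of the simulated front-end chain: rsector-level adder +
#' energy-winner readout (imitating Compton scatter recovery), Gaussian
#' energy blur (9.63% FWHM at 511 keV, scaling as 1/sqrt(E)), flat
#' detection efficiency, Gaussian timing blur, energy discriminator and
#' multi-window takeAllGoods coincidence sorting, plus the Lu-176
#' intrinsic-background singles rate of the LYSO crystals.
#'
#' @param energy_resolution_fwhm Fractional FWHM at 511 keV.
#' @param energy_window keV pair (lower, upper).
#' @param temporal_fwhm_ps Timing blur FWHM per single, ps.
#' @param detection_efficiency Per-single survival probability.
#' @param lu176_rate_khz Intrinsic background singles rate before the
#'   energy window, kHz over the whole scanner.
#' @param coincidence_window_2tau_ns Total coincidence window 2*tau, ns.
#' @param crystal_stopping Apply the energy-dependent LYSO stopping
#'   probability at detection.
#' @param acollinearity_fwhm_deg Gaussian photon acollinearity (0 = off).
#' @param kill_energy keV below which photons are terminated in transport
#'   (far below the 425 keV discriminator).
#' @param positron_yield Beta-plus branching of F-18.
#' @param halflife_min F-18 half-life, minutes.
#' @return An object of class `petchain_digitizer_config`.
#' @export
digitizer_config <- function(energy_resolution_fwhm = 0.0963,
                             energy_window = c(425, 650),
                             temporal_fwhm_ps = 268.7,
                             detection_efficiency = 0.98,
                             lu176_rate_khz = 1142,
                             coincidence_window_2tau_ns = 4.9,
                             crystal_stopping = TRUE,
                             acollinearity_fwhm_deg = 0,
                             kill_energy = 250,
                             positron_yield = 0.967,
                             halflife_min = 109.77) {
  if (energy_window[1] >= energy_window[2])
    stop("energy window lower bound must be below the upper bound")
  if (any(c(energy_resolution_fwhm, temporal_fwhm_ps, detection_efficiency,
            lu176_rate_khz, coincidence_window_2tau_ns) < 0))
    stop("rates and resolutions must be nonnegative")
  structure(list(
    energy_resolution_fwhm = energy_resolution_fwhm,
    energy_window = energy_window,
    temporal_fwhm_ps = temporal_fwhm_ps,
    detection_efficiency = detection_efficiency,
    lu176_rate_khz = lu176_rate_khz,
    coincidence_window_2tau_ns = coincidence_window_2tau_ns,
    multiples_policy = "takeAllGoods",
    readout_level = "rsector",
    readout_policy = "energy_winner",
    crystal_stopping = crystal_stopping,
    acollinearity_fwhm_deg = acollinearity_fwhm_deg,
    kill_energy = kill_energy,
    positron_yield = positron_yield,
    halflife_min = halflife_min), class = "petchain_digitizer_config")
}

sim_par_list <- function(cfg, duration, scatter_on, liner = TRUE,
                         liner_mu = 0.104) {
  list(duration = duration,
       energy_resolution_fwhm = cfg$energy_resolution_fwhm,
       energy_window_lo = cfg$energy_window[1],
       energy_window_hi = cfg$energy_window[2],
       temporal_fwhm_ps = cfg$temporal_fwhm_ps,
       detection_efficiency = cfg$detection_efficiency,
       scatter_on = scatter_on,
       kill_energy = cfg$kill_energy,
       liner_radius = 350, liner_thickness = 2,
       liner_mu = if (liner) liner_mu else 0,
       crystal_stopping = cfg$crystal_stopping,
       acollinearity_fwhm_deg = cfg$acollinearity_fwhm_deg)
}

#' Sample annihilation decays from a voxel phantom
#'
#' The number of beta-plus decays in the frame is Poisson with mean
#' `total activity x duration x positron yield x decimation`; emission
#' positions follow the activity grid (uniform jitter inside the voxel),
#' emission times are uniform in the frame, and the two photons are emitted
#' back to back.  `frame_start_min` applies the physical-decay factor
#' `2^(-t/T1/2)` to the rate for frames acquired after the reference time.
#'
#' @param phantom A [build_phantom()] object.
#' @param duration Frame duration, s.
#' @param cfg Digitizer/acquisition configuration.
#' @param decimation Desk-scale activity down-scaling factor in (0, 1].
#' @param frame_start_min Frame start relative to the activity reference,
#'   minutes.
#' @param seed RNG seed.
#' @return List with `pos` (n x 3 mm), `dir` (n x 3, photon 1; photon 2 is
#'   antiparallel), `time_ns`, and the realised decay count `n`.
#' @export
sample_annihilations <- function(phantom, duration, cfg = digitizer_config(),
                                 decimation = 1, frame_start_min = 0,
                                 seed = 1) {
  if (duration <= 0) stop("duration must be positive")
  set.seed(seed)
  rate <- phantom$total_activity_kBq * 1e3 * cfg$positron_yield *
    decimation * 2^(-frame_start_min / cfg$halflife_min)
  n <- stats::rpois(1, rate * duration)
  if (n == 0)
    return(list(pos = matrix(0, 0, 3), dir = matrix(0, 0, 3),
                time_ns = numeric(0), n = 0L))
  act <- as.numeric(phantom$activity)
  vox <- sample.int(length(act), n, replace = TRUE, prob = act)
  dm <- dim(phantom$activity)
  ix <- (vox - 1) %% dm[1]
  iy <- ((vox - 1) %/% dm[1]) %% dm[2]
  iz <- (vox - 1) %/% (dm[1] * dm[2])
  pos <- cbind(phantom$origin[1] + (ix + stats::runif(n)) * phantom$voxel[1],
               phantom$origin[2] + (iy + stats::runif(n)) * phantom$voxel[2],
               phantom$origin[3] + (iz + stats::runif(n)) * phantom$voxel[3])
  ct <- stats::runif(n, -1, 1)
  st <- sqrt(1 - ct^2)
  ph <- stats::runif(n, 0, 2 * pi)
  dir <- cbind(st * cos(ph), st * sin(ph), ct)
  list(pos = pos, dir = dir, time_ns = stats::runif(n, 0, duration * 1e9),
       n = n)
}

#' Transport photons through the phantom grid
#'
#' Woodcock (delta-tracking) transport with Klein-Nishina Compton sampling
#' and a small photoelectric branch; energies follow the Compton relation
#' and object scatters are counted per photon.
#'
#' @param pos,dir n x 3 start positions (mm) and directions.
#' @param phantom A [build_phantom()] object.
#' @param energy Start energies, keV (recycled).
#' @param scatter_on If `FALSE` every interaction terminates the photon
#'   (pure-absorption mode used for scatter-free reference runs).
#' @param kill_energy Termination energy, keV.
#' @param seed RNG seed.
#' @return List with exit `pos`, `dir`, `energy`, `n_scatters`, `alive`
#'   (0 = absorbed) and accumulated `path_mm`.
#' @export
transport_photons <- function(pos, dir, phantom, energy = 511,
                              scatter_on = TRUE, kill_energy = 250,
                              seed = 1) {
  cpp_transport_photons(pos, dir, rep_len(energy, nrow(pos)),
                        as.numeric(phantom$mu), dim(phantom$mu),
                        phantom$voxel, phantom$origin, scatter_on,
                        kill_energy, seed)
}

#' Digitizer chain: adder, energy-winner readout, efficiency, blur, window
#'
#' Per decay and per rsector, deposits are first summed per crystal
#' (adder); the crystal with the largest deposit carries the rsector's
#' total energy (energy-winner readout at the rsector level).  Each single
#' then survives with the detection efficiency, its energy is blurred with
#' the 1/sqrt(E)-scaled Gaussian resolution and must fall inside the
#' energy window, and its time is blurred with the timing resolution.
#'
#' @param hits Data frame with `decay_id`, `tax`, `ring`, `energy` (keV),
#'   `time_ns`, `n_scatters`.
#' @param cfg Digitizer configuration; set `energy_resolution_fwhm = 0` and
#'   `temporal_fwhm_ps = 0` for a blur-free chain.
#' @param scanner Scanner model.
#' @param seed RNG seed.
#' @return Singles data frame (`time_ns`, `tax`, `ring`, `energy`,
#'   `n_scatters`, `decay_id`).
#' @export
digitize <- function(hits, cfg = digitizer_config(), scanner = NULL,
                     seed = 1) {
  set.seed(seed)
  n_tax_sector <- if (is.null(scanner)) 16L else scanner$geom$n_tax_sector
  dt <- data.table::as.data.table(hits)
  dt[, rsector := tax %/% n_tax_sector]
  dt[, crystal_key := tax + 1e5 * ring]
  # adder: sum deposits per crystal within (decay, rsector)
  per_crystal <- dt[, list(energy = sum(energy), time_ns = min(time_ns),
                           n_scatters = max(n_scatters)),
                    by = list(decay_id, rsector, crystal_key)]
  # energy-winner readout at rsector level: winner crystal, total energy
  singles <- per_crystal[, {
    w <- which.max(energy)
    list(crystal_key = crystal_key[w], energy = sum(energy),
         time_ns = time_ns[w], n_scatters = max(n_scatters))
  }, by = list(decay_id, rsector)]
  n <- nrow(singles)
  keep <- stats::runif(n) < cfg$detection_efficiency
  singles <- singles[keep]
  n <- nrow(singles)
  if (cfg$energy_resolution_fwhm > 0) {
    sig <- cfg$energy_resolution_fwhm * sqrt(511 * singles$energy) / 2.3548
    singles[, energy := energy + sig * stats::rnorm(n)]
  }
  singles <- singles[energy >= cfg$energy_window[1] &
                     energy <= cfg$energy_window[2]]
  n <- nrow(singles)
  if (cfg$temporal_fwhm_ps > 0)
    singles[, time_ns := time_ns +
              (cfg$temporal_fwhm_ps / 2.3548) * stats::rnorm(n) / 1000]
  data.frame(time_ns = singles$time_ns,
             tax = as.integer(singles$crystal_key %% 1e5),
             ring = as.integer(singles$crystal_key %/% 1e5),
             energy = singles$energy,
             n_scatters = singles$n_scatters,
             decay_id = singles$decay_id)
}

#' Sample deposited energies of the Lu-176 intrinsic background
#'
#' A documented approximation of the LYSO self-counting spectrum: the
#' Lu-176 beta continuum (endpoint 593 keV, allowed shape) plus partial
#' local absorption of the 88/202/307 keV cascade gammas with fixed
#' absorption probabilities (0.9, 0.6, 0.45).
#'
#' @param n Number of samples.
#' @param seed RNG seed (uses the current RNG stream when `NULL`).
#' @return Deposited energies, keV.
#' @export
lu176_spectrum_sample <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  q <- 593
  tg <- seq(0.5, q - 0.5, by = 1)
  w <- sqrt(tg^2 + 2 * tg * 511) * (tg + 511) * (q - tg)^2
  beta <- sample(tg, n, replace = TRUE, prob = w) + stats::runif(n, -0.5, 0.5)
  g <- cbind(stats::rbinom(n, 1, 0.90) * 88,
             stats::rbinom(n, 1, 0.60) * 202,
             stats::rbinom(n, 1, 0.45) * 307)
  beta + rowSums(g)
}

#' Lu-176 background singles
#'
#' Poisson stream at the configured rate, uniform over crystals and time,
#' energies drawn from [lu176_spectrum_sample()] and then blurred and
#' windowed like any other single.
#'
#' @param cfg Digitizer configuration.
#' @param scanner Scanner model.
#' @param duration Frame duration, s.
#' @param decimation Rate scale factor.
#' @param seed RNG seed.
#' @return Singles data frame (negative `decay_id` marks Lu-176 origin).
#' @export
lu176_background <- function(cfg, scanner, duration, decimation = 1,
                             seed = 1) {
  set.seed(seed)
  n <- stats::rpois(1, cfg$lu176_rate_khz * 1e3 * duration * decimation)
  if (n == 0)
    return(data.frame(time_ns = numeric(0), tax = integer(0),
                      ring = integer(0), energy = numeric(0),
                      n_scatters = integer(0), decay_id = numeric(0)))
  e <- lu176_spectrum_sample(n)
  if (cfg$energy_resolution_fwhm > 0)
    e <- e + cfg$energy_resolution_fwhm * sqrt(511 * e) / 2.3548 *
      stats::rnorm(n)
  tax <- sample.int(scanner$spec$n_tax, n, replace = TRUE) - 1L
  ring <- sample.int(scanner$spec$n_rings, n, replace = TRUE) - 1L
  t <- stats::runif(n, 0, duration * 1e9)
  keep <- e >= cfg$energy_window[1] & e <= cfg$energy_window[2]
  data.frame(time_ns = t[keep], tax = tax[keep], ring = ring[keep],
             energy = e[keep], n_scatters = 0L,
             decay_id = -seq_len(sum(keep)))
}

#' Multi-window coincidence sorting with takeAllGoods
#'
#' Each single opens a tau window; every pair of singles within the total
#' 2*tau coincidence window and with rsector separation of at least the
#' minimum sector difference becomes a prompt.  Ground-truth labels:
#' `true` (same decay, no object scatter), `scattered` (same decay, at
#' least one object scatter), `random` (different decays or Lu-176
#' involvement).
#'
#' @param singles Singles data frame (any order; sorted internally).
#' @param cfg Digitizer configuration.
#' @param scanner Scanner model.
#' @return Coincidence data frame with crystal indices, energies, label and
#'   `tof_delta_ps` (time of single 1 minus single 2).
#' @export
sort_coincidences <- function(singles, cfg, scanner, minimal = FALSE) {
  s <- data.table::as.data.table(singles)
  data.table::setorder(s, time_ns)
  tau <- cfg$coincidence_window_2tau_ns / 2
  r <- cpp_sort_coincidences(s$time_ns, as.integer(s$tax),
                             as.integer(s$ring), as.numeric(s$decay_id),
                             as.integer(s$n_scatters), tau, scanner$geom)
  # orient each prompt by the canonical crystal order (smaller ring, then
  # smaller transaxial index first) so the TOF sign is detector-defined
  swap <- s$ring[r$j] < s$ring[r$i] |
    (s$ring[r$j] == s$ring[r$i] & s$tax[r$j] < s$tax[r$i])
  a <- ifelse(swap, r$j, r$i)
  b <- ifelse(swap, r$i, r$j)
  if (minimal)
    return(data.frame(tax1 = s$tax[a], ring1 = s$ring[a],
                      tax2 = s$tax[b], ring2 = s$ring[b],
                      label = c("true", "scattered", "random")[r$label]))
  data.frame(tax1 = s$tax[a], ring1 = s$ring[a],
             tax2 = s$tax[b], ring2 = s$ring[b],
             energy1 = s$energy[a], energy2 = s$energy[b],
             label = c("true", "scattered", "random")[r$label],
             lu176 = s$decay_id[a] < 0 | s$decay_id[b] < 0,
             n_scatters1 = s$n_scatters[a], n_scatters2 = s$n_scatters[b],
             tof_delta_ps = (s$time_ns[a] - s$time_ns[b]) * 1000)
}

#' End-to-end simulated acquisition
#'
#' Runs the fused decay-transport-digitizer chain in batches, adds the
#' Lu-176 background singles, sorts coincidences and tallies the
#' ground-truth summary.  `decimation` scales both the phantom activity and
#' the Lu-176 rate.
#'
#' @param phantom A [build_phantom()] object.
#' @param cfg Digitizer configuration.
#' @param scanner Scanner model.
#' @param duration Frame duration, s.
#' @param decimation Activity down-scaling factor in (0, 1].
#' @param seed RNG seed.
#' @param scatter_on Object scattering enabled.
#' @param include_lu176 Include the intrinsic background.
#' @param keep_singles Also return the singles table.
#' @param chunk Decays per transport batch.
#' @return An object of class `petchain_acquisition`: `events` (prompts),
#'   `singles_counts` (per-crystal singles, tax x ring matrix), `summary`
#'   (counts by label), plus the acquisition metadata.
#' @export
simulate_acquisition <- function(phantom, cfg, scanner, duration,
                                 decimation = 1, seed = 1,
                                 scatter_on = TRUE, include_lu176 = TRUE,
                                 keep_singles = FALSE, chunk = 5e6,
                                 liner = TRUE, crystal_eff = NULL,
                                 mu_voxel = 4, minimal_events = FALSE) {
  stopifnot(decimation > 0, decimation <= 1)
  set.seed(seed)
  rate <- phantom$total_activity_kBq * 1e3 * cfg$positron_yield * decimation
  n_decays <- stats::rpois(1, rate * duration)
  act <- as.numeric(phantom$activity)
  tot <- sum(act)
  parts <- list()
  if (n_decays > 0 && tot > 0) {
    prob <- act / tot
    par <- sim_par_list(cfg, duration, scatter_on, liner = liner)
    if (!is.null(crystal_eff)) par$crystal_eff <- as.numeric(crystal_eff)
    # transport attenuation on a coarser grid (mu is piecewise smooth)
    if (mu_voxel > max(phantom$voxel)) {
      dmu <- as.integer(pmax(ceiling(dim(phantom$mu) * phantom$voxel /
                                       mu_voxel), 1))
      mu_t <- resample_mean(phantom$mu, phantom$voxel, phantom$origin,
                            dmu, rep(mu_voxel, 3), phantom$origin)
      mu_vox <- rep(mu_voxel, 3); mu_org <- phantom$origin
    } else {
      mu_t <- phantom$mu; dmu <- dim(phantom$mu)
      mu_vox <- phantom$voxel; mu_org <- phantom$origin
    }
    offsets <- seq(0, n_decays - 1, by = chunk)
    for (ci in seq_along(offsets)) {
      nb <- min(chunk, n_decays - offsets[ci])
      parts[[ci]] <- data.table::as.data.table(cpp_simulate_batch(
        nb, prob, dim(phantom$activity), phantom$voxel, phantom$origin,
        as.numeric(mu_t), dmu, mu_vox, mu_org, scanner$geom, par,
        seed = abs(seed) * 2654435761 %% 2^31 + ci * 1000003,
        id_offset = offsets[ci]))
    }
  }
  singles <- if (length(parts)) data.table::rbindlist(parts) else
    data.table::data.table(time_ns = numeric(0), tax = integer(0),
                           ring = integer(0), energy = numeric(0),
                           n_scatters = integer(0), decay_id = numeric(0))
  parts <- NULL
  if (include_lu176 && cfg$lu176_rate_khz > 0) {
    lu <- lu176_background(cfg, scanner, duration, decimation,
                           seed = abs(seed) + 77)
    singles <- data.table::rbindlist(list(
      singles, data.table::as.data.table(lu)), use.names = TRUE)
    rm(lu)
  }
  n_singles <- nrow(singles)
  counts <- matrix(0, scanner$spec$n_tax, scanner$spec$n_rings)
  if (n_singles > 0) {
    tb <- tabulate(singles$tax + scanner$spec$n_tax * singles$ring + 1L,
                   nbins = scanner$spec$n_tax * scanner$spec$n_rings)
    counts <- matrix(tb, scanner$spec$n_tax, scanner$spec$n_rings)
  }
  events <- sort_coincidences(singles, cfg, scanner,
                              minimal = minimal_events)
  if (!keep_singles) { singles <- NULL; gc(verbose = FALSE) }
  summary <- list(
    n_decays = n_decays,
    n_singles = n_singles,
    prompts = nrow(events),
    trues = sum(events$label == "true"),
    scatters = sum(events$label == "scattered"),
    randoms = sum(events$label == "random"),
    lu176_involved = sum(events$lu176),
    duration = duration, decimation = decimation, seed = seed)
  out <- list(events = events, singles_counts = counts, summary = summary,
              duration = duration, decimation = decimation, seed = seed)
  if (keep_singles && !is.null(singles)) out$singles <- as.data.frame(singles)
  class(out) <- "petchain_acquisition"
  out
}
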