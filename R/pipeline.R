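#' Pipeline configuration
#'
#' Bundles every stage's settings; serialises losslessly through YAML and
#' carries an MD5 content hash that is stamped into all artifacts.
#'
#' @param phantom A [phantom_spec()] (or its argument list).
#' @param duration Frame duration, s.
#' @param decimation Activity down-scaling factor.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param phantom_voxel Rasterisation voxel, mm.
#' @param layout Arguments for [sinogram_layout()].
#' @param recon Arguments for [recon_config()].
#' @param digitizer Arguments for [digitizer_config()].
#' @param norm_decays Decays per normalisation-calibration source.
#' @param sss_iterations SSS iterations.
#' @param wcc Optional well-counter calibration factor applied to the
#'   final image.
#' @param tof Reconstruct the final image with TOF weighting.
#' @param tof_bins,tof_width TOF axis used for the prompt histogram and
#'   the reconstruction (bins x ps).
#' @return An object of class `petchain_pipeline_config`.
#' @export
pipeline_config <- function(phantom, duration = 600, decimation = 0.01,
                            seed = 1, phantom_voxel = 2,
                            layout = list(), recon = list(),
                            digitizer = list(), norm_decays = 1.6e8,
                            sss_iterations = 3, wcc = NULL,
                            tof = TRUE, tof_bins = 9L, tof_width = 545) {
  if (inherits(phantom, "petchain_phantom_spec")) phantom <- unclass(phantom)
  cfg <- list(phantom = phantom, duration = duration,
              decimation = decimation, seed = seed,
              phantom_voxel = phantom_voxel, layout = layout,
              recon = recon, digitizer = digitizer,
              norm_decays = norm_decays, sss_iterations = sss_iterations,
              wcc = wcc, tof = tof, tof_bins = as.integer(tof_bins),
              tof_width = tof_width)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "petchain_pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  cfg$hash <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101, norm = 202, sss = 303, wcc = 404)
  (abs(seed) %% 2^28) + unname(offs[stage])
}

#' Run the simulation-to-image-quality pipeline
#'
#' Stages: `simulate` (decay transport + digitizer + coincidence
#' sorting), `bin` (sinogram histogramming), `correct` (attenuation,
#' normalisation, randoms, iterative single-scatter estimation),
#' `reconstruct` (OS-EM + Gaussian post-filter, optional well-counter
#' scaling) and `evaluate` (NEMA image-quality metrics and the
#' estimated scatter fraction).  Stages run in order; earlier artifacts
#' can be injected through `state` to rerun later stages independently.
#'
#' @param config A [pipeline_config()].
#' @param scanner Scanner model (built once and shared).
#' @param stages Stages to run.
#' @param norm Precomputed `petchain_norm` (skips the calibration
#'   simulations, which otherwise run inside `correct`).
#' @param state Artifacts from a previous (partial) run.
#' @param workdir If set, artifacts are written there.
#' @param verbose Print stage progress.
#' @return An object of class `petchain_pipeline`: the accumulated
#'   artifacts plus per-stage counters.
#' @export
run_pipeline <- function(config, scanner = build_scanner(),
                         stages = c("simulate", "bin", "correct",
                                    "reconstruct", "evaluate"),
                         norm = NULL, state = list(), workdir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  st <- state
  st$config <- config
  cfgd <- do.call(digitizer_config, config$digitizer)
  layout <- do.call(sinogram_layout,
                    c(list(scanner = scanner), config$layout))
  use_tof <- isTRUE(config$tof)
  layout_tof <- if (use_tof)
    do.call(sinogram_layout,
            c(list(scanner = scanner), config$layout,
              list(tof_bins = config$tof_bins,
                   tof_width = config$tof_width))) else NULL
  rcfg <- do.call(recon_config, config$recon)
  pspec <- do.call(phantom_spec, config$phantom)
  scale <- config$duration * config$decimation
  if ("simulate" %in% stages) {
    say("stage simulate: %s, duration %gs, decimation %g",
        pspec$kind, config$duration, config$decimation)
    phantom <- build_phantom(pspec, voxel = config$phantom_voxel)
    st$phantom <- phantom
    st$acq <- simulate_acquisition(phantom, cfgd, scanner,
                                   duration = config$duration,
                                   decimation = config$decimation,
                                   seed = stage_seed(config$seed, "simulate"))
    say("  %d decays -> %d prompts (%d true / %d scatter / %d random)",
        st$acq$summary$n_decays, st$acq$summary$prompts,
        st$acq$summary$trues, st$acq$summary$scatters,
        st$acq$summary$randoms)
    if (!is.null(workdir))
      write_event_list(st$acq, file.path(workdir, "events.csv.gz"),
                       meta = list(hash = config$hash, seed = config$seed))
  }
  if ("bin" %in% stages) {
    if (is.null(st$acq)) stop("stage bin: missing acquisition artifact")
    say("stage bin: %d x %d x %d sinogram%s", layout$n_radial,
        layout$n_azimuthal, layout$n_planes,
        if (use_tof) sprintf(" x %d TOF bins", config$tof_bins) else "")
    if (use_tof) {
      nb <- bin_events(st$acq$events, layout_tof, scanner,
                       integer_counts = TRUE)
      st$prompts_tof <- nb$array
      st$n_binned <- nb$n_accepted
      ps <- 0
      page <- prod(dim(nb$array)[1:3])
      for (t in seq_len(dim(nb$array)[4]))
        ps <- ps + as.numeric(nb$array[(1 + (t - 1) * page):(t * page)])
      st$prompts <- array(ps, c(layout$n_radial, layout$n_azimuthal,
                                layout$n_planes))
      rm(ps)
    } else {
      nb <- bin_events(st$acq$events, layout, scanner)
      st$prompts <- nb$array
      st$n_binned <- nb$n_accepted
    }
    rm(nb); gc(verbose = FALSE)
  }
  if ("correct" %in% stages) {
    if (is.null(st$prompts)) stop("stage correct: missing prompt sinogram")
    if (is.null(st$phantom))
      st$phantom <- build_phantom(pspec, voxel = config$phantom_voxel)
    say("stage correct: attenuation")
    st$acf <- attenuation_correction_sinogram(st$phantom, scanner, layout)
    if (is.null(norm)) {
      say("stage correct: normalisation calibration (%g decays/source)",
          config$norm_decays)
      na <- normalisation_acquisitions(scanner, cfgd, layout,
                                       n_decays_central = config$norm_decays,
                                       n_decays_annulus = config$norm_decays,
                                       seed = stage_seed(config$seed, "norm"))
      norm <- estimate_normalisation(na$central, na$annulus, scanner, layout)
    }
    st$norm <- norm
    say("stage correct: randoms")
    st$randoms <- randoms_from_singles(st$acq$singles_counts,
                                       config$duration,
                                       cfgd$coincidence_window_2tau_ns,
                                       layout, scanner)
    say("stage correct: single scatter simulation (%d iterations)",
        config$sss_iterations)
    sss <- iterate_sss(st$prompts, st$randoms, st$acf, norm$eta,
                       st$phantom, scanner, layout, cfgd, rcfg,
                       n_iter = config$sss_iterations,
                       seed = stage_seed(config$seed, "sss"),
                       scale = scale,
                       scatter_pattern = norm$crystal_pair)
    st$scatter <- sss$scatter
    st$sss <- sss["beta"]
    if (use_tof) {
      # TOF profile of the scatter: model-based split of the fitted
      # (non-TOF) estimate across the TOF bins
      est_t <- sss_scatter_estimate(sss$last_image, st$phantom, scanner,
                                    layout_tof, cfgd, tof = TRUE,
                                    seed = stage_seed(config$seed, "sss"))
      up_t <- upsample_scatter(est_t, layout_tof)
      rm(est_t)
      ntof <- dim(up_t)[4]
      dim(up_t) <- c(prod(dim(up_t)[1:3]), ntof)
      tot <- rowSums(up_t)
      share <- ifelse(tot > 0, 1 / tot, 0) * up_t
      share[tot <= 0, ] <- 1 / ntof
      st$scatter_tof <- array(as.numeric(st$scatter) * share,
                              c(dim(st$scatter), ntof))
      rm(up_t, share); gc(verbose = FALSE)
    }
    rm(sss); gc(verbose = FALSE)
    if (!is.null(workdir))
      write_sinogram_set(list(layout = unclass(layout),
                              prompts = st$prompts, randoms = st$randoms,
                              scatter = st$scatter, acf = st$acf,
                              eta = norm$eta),
                         file.path(workdir, "sinograms.rds"),
                         meta = list(hash = config$hash))
  }
  if ("reconstruct" %in% stages) {
    if (is.null(st$scatter)) stop("stage reconstruct: missing corrections")
    say("stage reconstruct: OS-EM %d x %d + %g/%g mm filter",
        rcfg$n_iterations, rcfg$n_subsets, rcfg$postfilter_fwhm[1],
        rcfg$postfilter_fwhm[2])
    rec <- if (use_tof)
      osem_reconstruct(st$prompts_tof,
                       list(acf = st$acf, eta = st$norm$eta,
                            randoms = st$randoms,
                            scatter = st$scatter_tof),
                       scanner, layout_tof, rcfg, scale = scale)
    else
      osem_reconstruct(st$prompts,
                       list(acf = st$acf, eta = st$norm$eta,
                            randoms = st$randoms,
                            scatter = st$scatter),
                       scanner, layout, rcfg, scale = scale)
    rec <- gaussian_postfilter(rec, rcfg$postfilter_fwhm)
    if (!is.null(config$wcc)) rec$values <- rec$values * config$wcc
    st$recon <- rec
    st$prompts_tof <- NULL
    st$scatter_tof <- NULL
    gc(verbose = FALSE)
    if (!is.null(workdir))
      write_volume(rec, file.path(workdir, "recon.nii.gz"),
                   meta = list(hash = config$hash, seed = config$seed))
  }
  if ("evaluate" %in% stages) {
    if (is.null(st$recon)) stop("stage evaluate: missing reconstruction")
    say("stage evaluate: NEMA metrics")
    st$report <- nema_iq_report(st$recon, pspec)
    st$sf_estimated <- tryCatch(
      scatter_fraction(st$prompts, st$scatter, st$randoms),
      error = function(e) NA_real_)
    st$sf_truth <- with(st$acq$summary,
                        if (trues + scatters > 0)
                          100 * scatters / (trues + scatters) else NA_real_)
    if (!is.null(workdir)) {
      rep <- list(spheres = st$report$spheres,
                  lung = st$report$lung$delta_c,
                  sf_estimated = st$sf_estimated,
                  sf_truth = st$sf_truth, hash = config$hash)
      jsonlite::write_json(rep, file.path(workdir, "iq_report.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
  }
  class(st) <- "petchain_pipeline"
  st
}
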