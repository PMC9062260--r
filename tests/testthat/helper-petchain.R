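# Shared fixtures: built once per test run.
tsc <- build_scanner()
tlay <- sinogram_layout(tsc)
tcfg <- digitizer_config()

# Bare phantom-like object (no walls) for targeted geometry tests.
bare_phantom <- function(dims, voxel, mu_fill = 0, act_fill = 0) {
  structure(list(
    activity = array(act_fill, dims),
    mu = array(mu_fill, dims),
    material = array(0L, dims),
    voxel = rep(voxel, 3),
    origin = -dims * voxel / 2,
    materials = petchain_materials(),
    total_activity_kBq = sum(array(act_fill, dims)) * voxel^3 / 1000,
    spec = list(kind = "custom")),
    class = "petchain_phantom")
}

# Water cylinder mu grid (no walls), radius mm, full grid length mm.
water_cylinder_phantom <- function(radius = 100, length = 200, voxel = 2,
                                   act = 0, mu = 0.0958) {
  half <- radius + 10
  nx <- 2 * ceiling(half / voxel)
  nz <- 2 * ceiling((length / 2 + 10) / voxel)
  ph <- bare_phantom(c(nx, nx, nz), voxel)
  xs <- ph$origin[1] + (seq_len(nx) - 0.5) * voxel
  zs <- ph$origin[3] + (seq_len(nz) - 0.5) * voxel
  inside <- outer(xs^2, xs^2, `+`) <= radius^2
  for (k in which(abs(zs) <= length / 2)) {
    m <- ph$mu[, , k]; m[inside] <- mu; ph$mu[, , k] <- m
    a <- ph$activity[, , k]; a[inside] <- act; ph$activity[, , k] <- a
  }
  ph$total_activity_kBq <- sum(ph$activity) * voxel^3 / 1000
  ph
}

# cache for expensive shared artifacts within one test run
.petchain_test_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .petchain_test_cache))
    assign(key, force(expr), envir = .petchain_test_cache)
  get(key, envir = .petchain_test_cache)
}

# ---- shared heavy fixtures (computed once, reused across test files) -------

acceptance_norm <- function() cached("acc_norm", {
  na <- normalisation_acquisitions(tsc, tcfg, tlay,
                                   n_decays_central = 1e8,
                                   n_decays_annulus = 1e8,
                                   n_chunks = 5, seed = 301)
  estimate_normalisation(na$central, na$annulus, tsc, tlay)
})

# decimated NEMA IQ hot-background frame through the full pipeline
acceptance_nema_b <- function() cached("acc_nema_b", {
  cfgp <- pipeline_config(
    phantom = list(kind = "nema_iq", sphere_concentration = 32.6,
                   background_concentration = 3.7),
    duration = 600, decimation = 2.5e-3, seed = 401)
  run_pipeline(cfgp, tsc, norm = acceptance_norm(), verbose = FALSE)
})

# decimated NEMA IQ cold-background frame through the correction chain
acceptance_nema_cold <- function() cached("acc_nema_cold", {
  cfgp <- pipeline_config(
    phantom = list(kind = "nema_iq", sphere_concentration = 44.8,
                   background_concentration = 0),
    duration = 600, decimation = 6e-3, seed = 403)
  res <- run_pipeline(cfgp, tsc,
                      stages = c("simulate", "bin", "correct"),
                      norm = acceptance_norm(), verbose = FALSE)
  list(sf_est = scatter_fraction(res$prompts, res$scatter, res$randoms),
       sf_truth = with(res$acq$summary,
                       100 * scatters / (trues + scatters)),
       lu_fraction = with(res$acq$summary, 100 * lu176_involved / prompts))
})

# decimated small-sphere cylinder hot-background frame, full pipeline
acceptance_cyl_b <- function() cached("acc_cyl_b", {
  cfgp <- pipeline_config(
    phantom = list(kind = "ds_cylinder", sphere_concentration = 20.7,
                   background_concentration = 2.6),
    duration = 600, decimation = 2e-3, phantom_voxel = 1,
    sss_iterations = 2, tof = FALSE, seed = 405)
  run_pipeline(cfgp, tsc, norm = acceptance_norm(), verbose = FALSE)
})

# crystal-efficiency recovery experiment: planted ~N(1, 0.05^2)
# efficiencies, estimated back from the calibration acquisitions
norm_recovery <- function() cached("norm_recovery", {
  # planted spread is 5% relative, centred at 0.85 so that no crystal's
  # survival probability saturates (detection efficiency x crystal
  # efficiency must stay below 1)
  set.seed(71)
  eps_true <- matrix(pmax(stats::rnorm(tsc$spec$n_crystals, 0.85, 0.0425),
                          0.6),
                     tsc$spec$n_tax, tsc$spec$n_rings)
  na <- normalisation_acquisitions(tsc, tcfg, tlay,
                                   n_decays_central = 1.8e8,
                                   n_decays_annulus = 4e7,
                                   n_chunks = 8,
                                   seed = 73, crystal_eff = eps_true)
  nm <- estimate_normalisation(na$central, na$annulus, tsc, tlay)
  list(eps_true = eps_true, eps_est = nm$epsilon, norm = nm)
})

# well-counter round trip: calibrate on one cylinder, recover the
# concentration of a second acquisition of known concentration
wcc_roundtrip <- function() cached("wcc_roundtrip", {
  run_one <- function(conc, seed) {
    cfgp <- pipeline_config(
      phantom = list(kind = "uniform_cylinder",
                     background_concentration = conc,
                     radius = 95, length = 200),
      duration = 45, decimation = 8e-3, seed = seed,
      layout = list(n_radial = 176L, n_azimuthal = 136L),
      recon = list(image_dim = 96L),
      norm_decays = 4e7, sss_iterations = 1, tof = FALSE)
    run_pipeline(cfgp, tsc, norm = NULL, stages = c("simulate", "bin",
                 "correct", "reconstruct"), verbose = FALSE)
  }
  a <- run_one(4.4, 501)
  b <- run_one(2.2, 503)
  wcc <- well_counter_calibrate(a$recon, 4.4)
  mean_b <- well_counter_calibrate(b$recon, 1)$c_arb
  list(wcc = wcc$wcc, recovered_b = wcc$wcc * mean_b)
})

# centred point source acquisition (timing-resolution checks)
point_acq <- function() cached("acq_point", {
  ph <- water_cylinder_phantom(radius = 2, length = 2, voxel = 1,
                               act = 2500)
  simulate_acquisition(ph, tcfg, tsc, 4, seed = 12, include_lu176 = FALSE)
})

# SSS vs brute-force double-integration oracle on a point-in-sphere toy:
# emission sphere (r = 30 mm) centred in a water sphere (r = 80 mm).  The
# oracle evaluates the same single-scatter model on the same down-sampled
# fields, but integrates the scatter points exactly (dense subdivision of
# every scatter voxel, no random offsets) with independent R ray marching.
sss_oracle_cmp <- function() cached("sss_oracle_cmp", {
  dims <- c(90, 90, 90); voxel <- c(2, 2, 2); origin <- -dims * voxel / 2
  xs <- origin[1] + (seq_len(90) - 0.5) * 2
  r2xy <- outer(xs^2, xs^2, `+`)
  mu <- array(0, dims); em <- array(0, dims)
  for (k in seq_len(90)) {
    rr <- r2xy + xs[k]^2
    s <- mu[, , k]; s[rr <= 80^2] <- 0.0958; mu[, , k] <- s
    e <- em[, , k]; e[rr <= 30^2] <- 1; em[, , k] <- e
  }
  est <- sss_scatter_estimate(em, mu, tsc, tlay, tcfg, seed = 3,
                              voxel = voxel, origin = origin)
  got <- est$pair_total
  # oracle on the identical coarse fields
  emc <- est$grid$emission; muc <- est$grid$mu
  cdim <- est$grid$dim; cvox <- est$grid$voxel; corg <- est$grid$origin
  sel <- which(muc >= 0.04)
  det <- petchain:::coarse_detector(tsc)
  nc <- nrow(det$pos)
  cmb <- which(upper.tri(matrix(TRUE, nc, nc)), arr.ind = TRUE)
  sa <- det$tax[cmb[, 1]] %/% 2; sb <- det$tax[cmb[, 2]] %/% 2
  dsec <- pmin(abs(sa - sb), 34 - abs(sa - sb))
  x1 <- det$pos[cmb[, 1], 1]; y1 <- det$pos[cmb[, 1], 2]
  x2 <- det$pos[cmb[, 2], 1]; y2 <- det$pos[cmb[, 2], 2]
  phi <- atan2(y2 - y1, x2 - x1) %% pi
  sdist <- -x1 * sin(phi) + y1 * cos(phi)
  ok <- dsec >= 4 & abs(sdist) <= 350
  A <- cmb[ok, 1]; B <- cmb[ok, 2]
  skn <- function(E) {
    a <- E / 511; l <- log(1 + 2 * a)
    (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - l / a) +
      l / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2
  }
  kn_d <- function(E, c_) {
    f <- 1 / (1 + (E / 511) * (1 - c_)); f^2 * (f + 1 / f - (1 - c_^2))
  }
  eps_det <- function(E) {
    sig <- 0.0963 * sqrt(511 * E) / 2.3548
    acc <- pnorm((650 - E) / sig) - pnorm((425 - E) / sig)
    mul <- exp(stats::approx(log(c(100, 150, 200, 300, 400, 511, 650)),
                             log(c(7.8, 3.38, 1.85, 1.17, 0.95, 0.84,
                                   0.76)), xout = log(E), rule = 2)$y)
    acc * (1 - exp(-mul * 2.5))
  }
  e511 <- eps_det(511)
  # independent ray marching through a coarse grid (vectorised over rays)
  march <- function(vol, p, n_steps = 120) {
    # p: single point; integrates point -> every coarse crystal
    d <- sweep(det$pos, 2, p)
    L <- sqrt(rowSums(d^2))
    tq <- (seq_len(n_steps) - 0.5) / n_steps
    out <- numeric(nc)
    for (c_ in seq_len(nc)) {
      q <- outer(tq, d[c_, ]) + rep(p, each = n_steps)
      j <- floor(sweep(q, 2, corg, "-") %*% diag(1 / cvox)) + 1
      okq <- j[, 1] >= 1 & j[, 1] <= cdim[1] & j[, 2] >= 1 &
        j[, 2] <= cdim[2] & j[, 3] >= 1 & j[, 3] <= cdim[3]
      v <- rep(0, n_steps)
      v[okq] <- vol[j[okq, , drop = FALSE]]
      out[c_] <- mean(v) * L[c_]
    }
    out
  }
  # exact scatter-point integration: 2x2x2 subdivision of each voxel
  offs <- as.matrix(expand.grid(c(0.25, 0.75), c(0.25, 0.75),
                                c(0.25, 0.75)))
  tot <- 0
  for (v in sel) {
    iv <- c((v - 1) %% cdim[1],
            ((v - 1) %/% cdim[1]) %% cdim[2],
            (v - 1) %/% (cdim[1] * cdim[2]))
    muS <- muc[v]
    for (o in seq_len(nrow(offs))) {
      sp <- corg + (iv + offs[o, ]) * cvox
      lam <- march(emc, sp)
      mui <- 0.1 * march(muc, sp)
      dA <- sweep(det$pos, 2, sp)
      lA <- sqrt(rowSums(dA^2))
      uA <- dA / lA
      rn <- sqrt(det$pos[, 1]^2 + det$pos[, 2]^2)
      cobl <- abs(-(det$pos[, 1] / rn) * uA[, 1] -
                    (det$pos[, 2] / rn) * uA[, 2])
      cost <- -(uA[A, 1] * uA[B, 1] + uA[A, 2] * uA[B, 2] +
                  uA[A, 3] * uA[B, 3])
      Ep <- 511 / (2 - cost)
      kEp <- petchain:::mu_energy_scale(Ep)
      geo <- det$area[A] * cobl[A] * det$area[B] * cobl[B] /
        (4 * pi * lA[A]^2 * lA[B]^2)
      kn <- kn_d(511, cost) / (4 * pi * skn(511))
      common <- geo * muS * kn
      epd <- eps_det(Ep)
      tA <- lam[A] * exp(-mui[A]) * exp(-kEp * mui[B]) * e511 * epd * common
      tB <- lam[B] * exp(-mui[B]) * exp(-kEp * mui[A]) * e511 * epd * common
      tot <- tot + sum(tA + tB) / nrow(offs)
    }
  }
  list(got = got, oracle = tot)
})
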