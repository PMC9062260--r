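test_that("decay sampling follows activity, duration and physical decay", {
  ph0 <- bare_phantom(c(8, 8, 8), 10)
  s0 <- sample_annihilations(ph0, 60, tcfg, seed = 1)
  expect_equal(s0$n, 0L)
  expect_error(sample_annihilations(ph0, -1, tcfg), "positive")
  # Poisson mean: 157.2 MBq x 60 s x 0.967 checked at 1e-8 scale
  ph <- water_cylinder_phantom(radius = 102, length = 276, voxel = 4,
                               act = 157.2e6 / (pi * 10.2^2 * 27.6 * 1000))
  expect_equal(ph$total_activity_kBq, 157.2e3, tolerance = 0.02)
  s <- sample_annihilations(ph, 60, tcfg, decimation = 1e-8, seed = 2)
  mu <- ph$total_activity_kBq * 1e3 * 60 * 0.967 * 1e-8
  expect_lt(abs(s$n - mu), 4 * sqrt(mu))
  # positions land only where activity is positive
  j <- floor(sweep(s$pos, 2, ph$origin, "-") %*% diag(1 / ph$voxel)) + 1
  expect_true(all(ph$activity[j] > 0))
  # second frame 30 min later: rate scaled by 2^(-30/109.77)
  s1 <- sample_annihilations(ph, 60, tcfg, decimation = 3e-8, seed = 3)
  s2 <- sample_annihilations(ph, 60, tcfg, decimation = 3e-8,
                             frame_start_min = 30, seed = 3)
  ratio <- s2$n / s1$n
  expect_equal(ratio, 2^(-30 / 109.77), tolerance = 0.02)
})

test_that("transport through vacuum and slabs matches analytic attenuation", {
  ph0 <- bare_phantom(c(20, 20, 20), 10)
  n <- 50
  pos <- cbind(runif(n, -50, 50), runif(n, -50, 50), runif(n, -50, 50))
  dir <- matrix(rnorm(3 * n), ncol = 3)
  tr <- transport_photons(pos, dir, ph0, seed = 5)
  expect_true(all(tr$alive == 1))
  expect_true(all(tr$n_scatters == 0))
  expect_true(all(tr$energy == 511))
  expect_error(transport_photons(pos, dir * NA, ph0), "finite")
  # water slab: transmitted-unscattered fraction = exp(-mu L)
  ph <- bare_phantom(c(60, 40, 40), 5)
  ph$mu[ph$origin[1] + (seq_len(60) - 0.5) * 5 > -50 &
        ph$origin[1] + (seq_len(60) - 0.5) * 5 < 50, , ] <- 0.0958
  n <- 1e5
  tr <- transport_photons(cbind(rep(-140, n), 0, 0),
                          cbind(rep(1, n), 0, 0), ph, seed = 6)
  p <- mean(tr$alive == 1 & tr$n_scatters == 0)
  p_true <- exp(-0.0958 * 10)
  expect_lt(abs(p - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("Compton angles follow the Klein-Nishina distribution", {
  x <- petchain:::cpp_sample_kn(2e5, 511, 7)
  kn <- function(c_) {
    f <- 1 / (1 + (1 - c_))
    f^2 * (f + 1 / f - (1 - c_^2))
  }
  br <- seq(-1, 1, length.out = 51)
  h <- hist(x, breaks = br, plot = FALSE)$counts
  p <- vapply(seq_len(50), function(i)
    stats::integrate(kn, br[i], br[i + 1])$value, numeric(1))
  p <- p / sum(p)
  chi <- sum((h - 2e5 * p)^2 / (2e5 * p))
  expect_gt(stats::pchisq(chi, 49, lower.tail = FALSE), 0.01)
})

test_that("digitizer applies adder, energy-winner readout, blur and window", {
  blur_off <- digitizer_config(energy_resolution_fwhm = 0,
                               temporal_fwhm_ps = 0,
                               detection_efficiency = 1)
  # a single 300 keV deposit is rejected by the 425 keV threshold
  h1 <- data.frame(decay_id = 0, tax = 10, ring = 5, energy = 300,
                   time_ns = 0, n_scatters = 0)
  expect_equal(nrow(digitize(h1, blur_off, tsc)), 0)
  # two deposits in one rsector: single at the winner crystal, summed energy
  h2 <- data.frame(decay_id = c(1, 1), tax = c(3, 9), ring = c(5, 7),
                   energy = c(180, 331), time_ns = c(0, 0.1),
                   n_scatters = c(0, 0))
  s2 <- digitize(h2, blur_off, tsc)
  expect_equal(nrow(s2), 1)
  expect_equal(s2$tax, 9)
  expect_equal(s2$ring, 7)
  expect_equal(s2$energy, 511)
  # window acceptance of blurred 511 keV deposits: Phi(6.65) - Phi(-4.115)
  n <- 2e5
  h3 <- data.frame(decay_id = seq_len(n), tax = 0, ring = 0, energy = 511,
                   time_ns = 0, n_scatters = 0)
  s3 <- digitize(h3, digitizer_config(detection_efficiency = 1), tsc,
                 seed = 8)
  sig <- 0.0963 * 511 / 2.3548
  p_true <- pnorm((650 - 511) / sig) - pnorm((425 - 511) / sig)
  expect_lt(abs(nrow(s3) / n - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("Lu-176 background is a uniform Poisson stream with the set rate", {
  cfg0 <- digitizer_config(lu176_rate_khz = 0)
  expect_equal(nrow(lu176_background(cfg0, tsc, 1)), 0)
  # pre-window rate: test with a wide-open window
  wide <- digitizer_config(energy_window = c(0.1, 5000),
                           energy_resolution_fwhm = 0)
  lu <- lu176_background(wide, tsc, 1, seed = 9)
  mu <- 1142e3
  expect_lt(abs(nrow(lu) - mu), 4 * sqrt(mu))
  # uniformity over rsectors (chi-squared on a multinomial)
  cnt <- tabulate(lu$tax %/% 16 + 1, 34)
  chi <- sum((cnt - mean(cnt))^2 / mean(cnt))
  expect_gt(stats::pchisq(chi, 33, lower.tail = FALSE), 1e-4)
  expect_true(all(lu$decay_id < 0))
})

test_that("coincidence sorter implements the multi-window takeAllGoods policy", {
  mk <- function(t, tax) data.frame(time_ns = t, tax = tax, ring = 5,
                                    energy = 511, n_scatters = 0,
                                    decay_id = seq_along(t))
  # two singles 10 ns apart: no coincidence
  expect_equal(nrow(sort_coincidences(mk(c(0, 10), c(0, 272)), tcfg, tsc)), 0)
  # three mutually-in-window goods in rsectors 0, 10, 20: 3 prompts
  ev <- sort_coincidences(mk(c(0, 1, 2), c(8, 168, 328)), tcfg, tsc)
  expect_equal(nrow(ev), 3)
  # minimum sector difference: rsectors 0 and 2 give no prompt
  expect_equal(nrow(sort_coincidences(mk(c(0, 1), c(8, 40)), tcfg, tsc)), 0)
  # unsorted input is handled by sorting internally
  ev2 <- sort_coincidences(mk(c(2, 0, 1), c(328, 8, 168)), tcfg, tsc)
  expect_equal(nrow(ev2), 3)
})

test_that("acquisition labels partition the prompts and are reproducible", {
  acq <- cached("acq_cyl_small", {
    ph <- build_phantom(phantom_spec("uniform_cylinder",
                                     background_concentration = 20,
                                     radius = 100, length = 200), voxel = 2)
    simulate_acquisition(ph, tcfg, tsc, 60, decimation = 4e-3, seed = 17)
  })
  s <- acq$summary
  expect_equal(s$prompts, s$trues + s$scatters + s$randoms)
  expect_gt(s$scatters, 0)
  expect_equal(nrow(acq$events), s$prompts)
  expect_equal(sum(acq$singles_counts), s$n_singles)
  # determinism
  ph <- build_phantom(phantom_spec("uniform_cylinder",
                                   background_concentration = 20,
                                   radius = 100, length = 200), voxel = 2)
  a2 <- simulate_acquisition(ph, tcfg, tsc, 60, decimation = 1e-3, seed = 19)
  a3 <- simulate_acquisition(ph, tcfg, tsc, 60, decimation = 1e-3, seed = 19)
  expect_identical(a2$events, a3$events)
})

test_that("scatter-free runs have zero ground-truth scatter fraction", {
  ph <- water_cylinder_phantom(radius = 100, length = 200, voxel = 2,
                               act = 10)
  acq <- simulate_acquisition(ph, tcfg, tsc, 60, decimation = 2e-3,
                              seed = 23, scatter_on = FALSE,
                              include_lu176 = FALSE)
  expect_gt(acq$summary$prompts, 0)
  expect_equal(acq$summary$scatters, 0)
})

test_that("simulated scatter fraction grows with phantom diameter", {
  sf <- vapply(c(50, 100, 150), function(r) {
    ph <- water_cylinder_phantom(radius = r, length = 200, voxel = 4,
                                 act = 10)
    a <- simulate_acquisition(ph, tcfg, tsc, 60, decimation = 1e-3,
                              seed = 29, include_lu176 = FALSE)
    with(a$summary, 100 * scatters / (trues + scatters))
  }, numeric(1))
  expect_true(all(diff(sf) > 0))
})

test_that("true-coincidence timing difference has the coincidence resolution", {
  acq <- point_acq()
  tt <- acq$events$tof_delta_ps[acq$events$label == "true"]
  expect_gt(length(tt), 5000)
  fwhm <- 2.3548 * sd(tt)
  expect_lt(abs(fwhm - sqrt(2) * 268.7) / (sqrt(2) * 268.7), 0.05)
})
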