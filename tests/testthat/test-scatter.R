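test_that("scatter estimate is empty without emission or scatter points", {
  dims <- c(64, 64, 40); voxel <- c(10, 10, 5)
  origin <- -dims * voxel / 2
  mu <- array(0.0958, dims)
  em0 <- array(0, dims)
  est <- sss_scatter_estimate(em0, mu, tsc, tlay, tcfg, seed = 1,
                              voxel = voxel, origin = origin)
  expect_equal(sum(est$coarse), 0)
  # a coarse voxel below the 0.04 1/cm threshold contributes no point
  mu_low <- array(0.03, dims)
  em <- array(1, dims)
  est2 <- sss_scatter_estimate(em, mu_low, tsc, tlay, tcfg, seed = 1,
                               voxel = voxel, origin = origin)
  expect_equal(nrow(est2$points), 0)
  expect_equal(sum(est2$coarse), 0)
})

test_that("up-sampling reproduces constants and the interpolants hit nodes", {
  est <- sss_scatter_estimate(array(0, c(8, 8, 4)), array(0, c(8, 8, 4)),
                              tsc, tlay, tcfg, seed = 1,
                              voxel = c(80, 80, 50), origin = c(-320, -320, -100))
  est$coarse[] <- 3.7
  up <- upsample_scatter(est, tlay)
  expect_equal(range(up), c(3.7, 3.7), tolerance = 1e-9)
  # interpolation matrices are exact at their own nodes
  x <- c(0, 1, 2.5, 4, 7)
  expect_equal(petchain:::spline_matrix(x, x), diag(5), tolerance = 1e-12)
  expect_equal(petchain:::linear_periodic_matrix(34, 34, pi), diag(34),
               tolerance = 1e-12)
  # azimuthal linear ramp reproduced exactly away from the periodic seam
  M <- petchain:::linear_periodic_matrix(34, 272, pi)
  xi <- (seq_len(34) - 0.5) * pi / 34
  xo <- (seq_len(272) - 0.5) * pi / 272
  ramp <- M %*% xi
  interior <- xo > xi[1] & xo < xi[34]
  expect_equal(ramp[interior], xo[interior], tolerance = 1e-12)
})

test_that("scatter estimate matches a brute-force integration oracle", {
  cmp <- sss_oracle_cmp()
  expect_equal(cmp$got / cmp$oracle, 1, tolerance = 0.02)
})

test_that("tail fitting recovers the scatter scale with zero intercept", {
  set.seed(5)
  dims <- c(40, 16, 8)
  s <- array(runif(prod(dims), 1, 5), dims)
  acf <- array(1, dims)
  acf[10:30, , ] <- 5   # "object" region excluded from the tails
  # y identical to s on the tails: beta = 1, q = 0
  f1 <- fit_scatter_tails(s, s, acf)
  expect_equal(f1$beta, 1, tolerance = 1e-12)
  expect_equal(f1$q, 0)
  expect_false(any(f1$tail_mask[10:30, , ]))
  # y = 2 s + Poisson noise: beta near 2 within 3 standard errors
  y <- array(rpois(prod(dims), 2 * s), dims)
  f2 <- fit_scatter_tails(s, y, acf)
  w <- f2$tail_mask
  se <- sqrt(sum(s[w]^2 * 2 * s[w])) / sum(s[w]^2)
  expect_lt(abs(f2$beta - 2), 3 * se)
  # intercept forced to zero without prompt gamma, free otherwise
  f3 <- fit_scatter_tails(s, 2 * s + 5, acf, prompt_gamma = FALSE)
  expect_equal(f3$q, 0)
  f4 <- fit_scatter_tails(s, 2 * s + 5, acf, prompt_gamma = TRUE)
  expect_equal(f4$q, 5, tolerance = 1e-6)
  expect_equal(f4$beta, 2, tolerance = 1e-6)
  expect_error(fit_scatter_tails(s, y, array(10, dims)), "empty")
})

test_that("iterative SSS averages the first two iterations and nulls out on scatter-free data", {
  slay <- sinogram_layout(tsc, n_radial = 64L, n_azimuthal = 32L)
  scfg <- recon_config(image_dim = 48L, n_iterations = 2L)
  run <- cached("sss_iter_run", {
    ph <- water_cylinder_phantom(radius = 100, length = 200, voxel = 2,
                                 act = 10)
    acq <- simulate_acquisition(ph, tcfg, tsc, 60, decimation = 5e-3,
                                seed = 41, include_lu176 = FALSE)
    y <- bin_events(acq$events, slay, tsc)$array
    acf <- attenuation_correction_sinogram(ph, tsc, slay)
    rnd <- randoms_from_singles(acq$singles_counts, 60, 4.9, slay, tsc)
    sss <- iterate_sss(y, rnd, acf, NULL, ph, tsc, slay, tcfg, scfg,
                       n_iter = 2, seed = 43, scale = 0.3)
    list(acq = acq, y = y, acf = acf, rnd = rnd, sss = sss, ph = ph)
  })
  expect_equal(run$sss$scatter,
               (run$sss$iterations[[1]] + run$sss$iterations[[2]]) / 2,
               tolerance = 1e-12)
  expect_error(iterate_sss(run$y, run$rnd, run$acf, NULL, run$ph, tsc,
                           slay, tcfg, scfg, n_iter = 0), "n_iter")
  # scatter-free acquisition: fitted scatter total < 2% of the trues
  acq0 <- simulate_acquisition(run$ph, tcfg, tsc, 60, decimation = 5e-3,
                               seed = 47, scatter_on = FALSE,
                               include_lu176 = FALSE)
  y0 <- bin_events(acq0$events, slay, tsc)$array
  rnd0 <- randoms_from_singles(acq0$singles_counts, 60, 4.9, slay, tsc)
  sss0 <- iterate_sss(y0, rnd0, run$acf, NULL, run$ph, tsc, slay, tcfg,
                      scfg, n_iter = 1, seed = 49, scale = 0.3)
  expect_lt(sum(sss0$scatter), 0.02 * acq0$summary$trues)
})

test_that("TOF-resolved estimates collapse to the non-TOF estimate", {
  tofl <- sinogram_layout(tsc, tof_bins = 29L)
  dims <- c(64, 64, 40); voxel <- c(10, 10, 5); origin <- -dims * voxel / 2
  mu <- array(0, dims); em <- array(0, dims)
  xs <- origin[1] + (seq_len(64) - 0.5) * 10
  r2 <- outer(xs^2, xs^2, `+`)
  for (k in 15:26) {
    s <- mu[, , k]; s[r2 <= 100^2] <- 0.0958; mu[, , k] <- s
    e <- em[, , k]; e[r2 <= 100^2] <- 1; em[, , k] <- e
  }
  est_tof <- sss_scatter_estimate(em, mu, tsc, tofl, tcfg, tof = TRUE,
                                  seed = 11, voxel = voxel, origin = origin)
  est_0 <- sss_scatter_estimate(em, mu, tsc, tofl, tcfg, tof = FALSE,
                                seed = 11, voxel = voxel, origin = origin)
  expect_equal(dim(est_tof$coarse)[4], 29)
  tof_sum <- apply(est_tof$coarse, 1:3, sum)
  expect_equal(tof_sum, est_0$coarse[, , , 1], tolerance = 0.02)
})
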