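test_that("Siddon ray sums match analytic and dense-sampling oracles", {
  ph <- water_cylinder_phantom(radius = 100, length = 200, voxel = 1)
  # ray missing the grid
  expect_equal(siddon_ray_sum(ph, c(500, 500, 0), c(500, 500, 100)), 0)
  # coincident endpoints
  expect_equal(siddon_ray_sum(ph, c(0, 0, 0), c(0, 0, 0)), 0)
  # 20 cm diametral chord through mu = 0.0958 water
  v <- siddon_ray_sum(ph, c(-150, 0, 0), c(150, 0, 0))
  expect_equal(v, 0.0958 * 20, tolerance = 0.01)
  # random-volume oracle: dense sampling
  set.seed(1)
  dims <- c(24L, 24L, 24L)
  vol <- array(runif(prod(dims)), dims)
  voxel <- c(3, 3, 3); origin <- -dims * voxel / 2
  n <- 100
  P0 <- cbind(runif(n, -60, 60), runif(n, -60, 60), runif(n, -60, 60))
  P1 <- cbind(runif(n, -60, 60), runif(n, -60, 60), runif(n, -60, 60))
  got <- siddon_ray_sum(vol, P0, P1, voxel, origin)
  ns <- 2e4
  t <- (seq_len(ns) - 0.5) / ns
  oracle <- vapply(seq_len(n), function(i) {
    p <- outer(t, P1[i, ] - P0[i, ]) + rep(P0[i, ], each = ns)
    j <- floor(sweep(p, 2, origin, "-") %*% diag(1 / voxel)) + 1
    ok <- j[, 1] >= 1 & j[, 1] <= dims[1] & j[, 2] >= 1 & j[, 2] <= dims[2] &
      j[, 3] >= 1 & j[, 3] <= dims[3]
    L <- sqrt(sum((P1[i, ] - P0[i, ])^2))
    vals <- rep(0, ns)
    vals[ok] <- vol[cbind(j[ok, 1], j[ok, 2], j[ok, 3])]
    0.1 * mean(vals) * L
  }, numeric(1))
  rel <- abs(got - oracle) / pmax(oracle, 1e-9)
  expect_lt(stats::median(rel), 1e-3)
  expect_lt(max(rel[oracle > 0.1]), 5e-3)
})

test_that("attenuation correction factors behave like exp(mu line integrals)", {
  lay <- sinogram_layout(tsc, n_radial = 50L, n_azimuthal = 16L)
  empty <- bare_phantom(c(20, 20, 20), 10)
  acf0 <- attenuation_correction_sinogram(empty, tsc, lay)
  expect_true(all(acf0 == 1))
  ph <- water_cylinder_phantom(radius = 100, length = 240, voxel = 2)
  acf <- attenuation_correction_sinogram(ph, tsc, lay)
  expect_true(all(acf >= 1))
  # central bin of the central plane: 20 cm chord
  mid <- acf[, 8, 36]
  expect_equal(max(mid), exp(0.0958 * 20), tolerance = 0.03)
  # monotone nonincreasing with radial offset (within half the cylinder)
  prof <- mid[26:50]
  expect_true(all(diff(prof) < 1e-6))
  # log(acf) scales linearly with mu
  ph2 <- ph; ph2$mu <- 2 * ph$mu
  acf2 <- attenuation_correction_sinogram(ph2, tsc, lay)
  expect_equal(log(acf2), 2 * log(acf), tolerance = 1e-9)
})

test_that("randoms-from-singles follows the 2 tau S1 S2 / T law", {
  n_tax <- tsc$spec$n_tax; n_rings <- tsc$spec$n_rings
  counts <- matrix(0, n_tax, n_rings)
  expect_true(all(randoms_from_singles(counts, 600, 4.9, tlay, tsc) == 0))
  # single crystal pair: closed form 2*4.9ns*1e6*1e6/600s = 8.17 counts
  counts[1 + 0, 1 + 18] <- 1e6     # tax 0, ring 18
  counts[1 + 272, 1 + 18] <- 1e6   # opposite crystal
  r <- randoms_from_singles(counts, 600, 4.9, tlay, tsc)
  expect_equal(sum(r), 4.9e-9 * 1e6 * 1e6 / 600, tolerance = 1e-9)
  expect_equal(sum(r), 8.1667, tolerance = 1e-3)
  # bilinearity: doubling all singles quadruples every bin
  r2 <- randoms_from_singles(2 * counts, 600, 4.9, tlay, tsc)
  expect_equal(r2, 4 * r, tolerance = 1e-12)
  expect_error(randoms_from_singles(counts, 0, 4.9, tlay, tsc), "positive")
})

test_that("randoms binning agrees with brute-force pair enumeration", {
  set.seed(3)
  n_tax <- tsc$spec$n_tax; n_rings <- tsc$spec$n_rings
  counts <- matrix(0, n_tax, n_rings)
  sel <- cbind(sample(n_tax, 25), sample(n_rings, 25, TRUE))
  counts[sel] <- stats::runif(25, 1e4, 1e6)
  r <- randoms_from_singles(counts, 600, 4.9, tlay, tsc)
  # brute force over the 25 active crystals
  tot <- 0
  for (i in 1:24) for (j in (i + 1):25) {
    b <- lor_to_bin(sel[i, 1] - 1, sel[i, 2] - 1,
                    sel[j, 1] - 1, sel[j, 2] - 1, tlay, tsc)
    if (b$accepted) tot <- tot + 4.9e-9 * counts[sel[i, , drop = FALSE]] *
        counts[sel[j, , drop = FALSE]] / 600
  }
  expect_equal(sum(r), tot, tolerance = 1e-9)
})

test_that("well-counter calibration is the concentration / image-mean ratio", {
  dims <- c(40, 40, 30); voxel <- c(5, 5, 5); origin <- -dims * voxel / 2
  img <- array(4.4, dims)
  w <- well_counter_calibrate(img, 4.4, roi_radius = 60, z_extent = 100,
                              voxel = voxel, origin = origin)
  expect_equal(w$wcc, 1, tolerance = 1e-12)
  w2 <- well_counter_calibrate(2 * img, 4.4, roi_radius = 60, z_extent = 100,
                               voxel = voxel, origin = origin)
  expect_equal(w2$wcc, 0.5, tolerance = 1e-12)
  expect_error(well_counter_calibrate(0 * img, 4.4, voxel = voxel,
                                      origin = origin), "zero")
})

test_that("normalisation components multiply exactly into eta", {
  nm <- acceptance_norm()
  nr <- tlay$n_radial; na_ <- tlay$n_azimuthal; np <- tlay$n_planes
  period <- nm$interference_period
  vp <- (seq_len(na_) - 1) %% period
  f_arr <- array(t(nm$f_interference[vp + 1, , drop = FALSE]),
                 c(nr, na_, np))
  eta_re <- nm$crystal_pair * rep(nm$g_axial, each = nr * na_) *
    array(nm$r_radial, c(nr, na_, np)) * f_arr
  expect_equal(eta_re, nm$eta, tolerance = 1e-12)
  expect_true(all(nm$eta[nm$support] >= 0))
})

test_that("a uniform detector yields near-unit axial components", {
  nm <- acceptance_norm()
  expect_lt(max(abs(nm$b_axial - 1)), 0.05)
  expect_lt(max(abs(nm$g_axial - 1)), 0.15)
  expect_equal(mean(nm$epsilon), 1, tolerance = 0.01)
})
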