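test_that("scatter fraction arithmetic follows S / (T + S)", {
  expect_equal(scatter_fraction(100, 0, 0), 0)
  expect_equal(scatter_fraction(100, 35, 0), 35)
  expect_equal(scatter_fraction(120, 35, 20), 35)
  expect_error(scatter_fraction(10, 0, 10), "undefined")
  expect_error(scatter_fraction(-1, 0, 0), "nonnegative")
})

test_that("CRC, SNR and BV follow their defining ratios", {
  expect_equal(crc(9 * 2, 2, 9), 100)
  expect_equal(crc(2, 2, 9), 0)
  expect_equal(crc(5 * 2, 2, 9), 50)
  expect_error(crc(1, 0, 9), "positive")
  expect_error(crc(1, 1, 1), "exceed")
  expect_equal(snr(10, 2, 2), 4)
  expect_equal(snr(2, 2, 1), 0)
  expect_error(snr(1, 1, 0), "positive")
  expect_equal(background_variability(c(1, 2, 3)), 50)
  expect_equal(background_variability(rep(4, 60)), 0)
  x <- runif(60, 1, 2)
  expect_equal(background_variability(10 * x), background_variability(x))
  expect_error(background_variability(1), "two")
})

test_that("SNR on a planted sphere matches a hand computation", {
  dims <- c(60, 60, 21); voxel <- c(4, 4, 4); origin <- -dims * voxel / 2
  set.seed(31)
  img <- array(rnorm(prod(dims), 10, 1), dims)
  # plant a 40 mm sphere of value 30 at the centre
  xs <- origin[1] + (seq_len(60) - 0.5) * 4
  zs <- origin[3] + (seq_len(21) - 0.5) * 4
  for (k in seq_len(21)) {
    m <- outer(xs^2, xs^2, `+`) + zs[k]^2 <= 20^2
    a <- img[, , k]; a[m] <- 30; img[, , k] <- a
  }
  s_mean <- roi_mean(img, 0, 0, 0, 40, voxel = voxel, origin = origin)
  b_mean <- roi_mean(img, 80, 0, 0, 40, voxel = voxel, origin = origin)
  rv <- roi_voxels(dims, voxel, origin, 80, 0, 0, 40)
  sig <- sd(img[, , rv$k][rv$mask])
  expect_equal(s_mean, 30, tolerance = 1e-6)
  expect_equal(snr(s_mean, b_mean, sig), (30 - b_mean) / sig)
})

test_that("residual lung error is 100% for an uncorrected insert and ~0 when cold", {
  dims <- c(60, 60, 71); voxel <- c(4, 4, 2.65); origin <- -dims * voxel / 2
  img <- array(5, dims)
  r <- residual_lung_error(img, b37 = 5, voxel = voxel, origin = origin)
  expect_equal(r$delta_c, 100)
  expect_equal(length(r$per_slice), 60)
  img2 <- img
  xs <- origin[1] + (seq_len(60) - 0.5) * 4
  hole <- outer(xs^2, xs^2, `+`) <= 20^2
  for (k in seq_len(71)) { a <- img2[, , k]; a[hole] <- 0; img2[, , k] <- a }
  r2 <- residual_lung_error(img2, b37 = 5, voxel = voxel, origin = origin)
  expect_equal(r2$delta_c, 0)
  expect_error(residual_lung_error(img, b37 = 0, voxel = voxel,
                                   origin = origin), "positive")
})

test_that("line profiles sample trilinearly with reversal symmetry", {
  dims <- c(30, 30, 30); voxel <- c(4, 4, 4); origin <- -dims * voxel / 2
  img <- array(7, dims)
  pr <- line_profile(img, c(-40, 0, 0), c(40, 0, 0), spacing = 2,
                     voxel = voxel, origin = origin)
  expect_true(all(abs(pr$value - 7) < 1e-12))
  expect_false(any(pr$clipped))
  # reversal symmetry
  img2 <- array(runif(prod(dims)), dims)
  p1 <- line_profile(img2, c(-40, 8, -12), c(40, -16, 20), spacing = 2,
                     voxel = voxel, origin = origin)
  p2 <- line_profile(img2, c(40, -16, 20), c(-40, 8, -12), spacing = 2,
                     voxel = voxel, origin = origin)
  expect_equal(p1$value, rev(p2$value), tolerance = 1e-12)
  # out-of-volume samples are flagged
  p3 <- line_profile(img, c(0, 0, 0), c(200, 0, 0), spacing = 4,
                     voxel = voxel, origin = origin)
  expect_true(any(p3$clipped))
})

test_that("a profile through a planted 37 mm sphere crosses half-max near +-18.5 mm", {
  dims <- c(101, 101, 41); voxel <- c(2, 2, 2); origin <- -dims * voxel / 2
  img <- array(0, dims)
  xs <- origin[1] + (seq_len(101) - 0.5) * 2
  zs <- origin[3] + (seq_len(41) - 0.5) * 2
  for (k in seq_len(41)) {
    m <- outer(xs^2, xs^2, `+`) + zs[k]^2 <= 18.5^2
    a <- img[, , k]; a[m] <- 1; img[, , k] <- a
  }
  pr <- line_profile(img, c(-50, 1, 1), c(50, 1, 1), spacing = 0.5,
                     voxel = voxel, origin = origin)
  cross <- pr$distance_mm[pr$value >= 0.5] - 50
  expect_lt(abs(min(cross) + 18.5), 2.5)
  expect_lt(abs(max(cross) - 18.5), 2.5)
})

test_that("background ROI placement respects the NEMA clearance rules", {
  for (kind in c("nema_iq", "ds_cylinder")) {
    spec <- phantom_spec(kind, sphere_concentration = 1,
                         background_concentration = 1)
    bg <- nema_background_rois(kind)
    expect_equal(nrow(bg$centres), 12)
    expect_equal(length(bg$slice_z), 5)
    cen <- petchain:::sphere_centres(spec)
    rad <- spec$sphere_diameters / 2
    roi_r <- max(spec$sphere_diameters) / 2
    for (j in seq_len(12)) {
      p <- bg$centres[j, ]
      # clearance from every sphere (largest ROI case)
      d <- sqrt((cen[, 1] - p[1])^2 + (cen[, 2] - p[2])^2)
      expect_true(all(d >= rad + 15 + roi_r - 1e-9))
      # clearance from the phantom wall and the lung insert
      if (kind == "nema_iq") {
        shrink <- 1 - (15 + roi_r) / 147
        expect_true(petchain:::nema_body_inside(p[1] / shrink,
                                                p[2] / shrink))
        expect_true(sqrt(sum(p^2)) >= 25 + 15 + roi_r)
      } else {
        expect_lte(sqrt(sum(p^2)), spec$radius - 15 - roi_r)
      }
    }
  }
})

test_that("an exact reconstruction yields perfect NEMA metrics", {
  spec <- phantom_spec("nema_iq", sphere_concentration = 32.6,
                      background_concentration = 3.7)
  ph <- build_phantom(spec, voxel = 1)
  rec <- structure(list(values = ph$activity, voxel = ph$voxel,
                        origin = ph$origin, scale = 1),
                   class = "petchain_recon")
  rep <- nema_iq_report(rec, spec)
  # centre-sampled voxelisation: sub-voxel edge effects below 2%
  expect_equal(rep$spheres$crc, rep(100, 6), tolerance = 0.02)
  expect_lt(max(rep$spheres$bv), 1e-9)
  expect_equal(rep$lung$delta_c, 0, tolerance = 1e-12)
  expect_equal(rep$sbr, 32.6 / 3.7)
})

test_that("bundled reference scatter fractions reproduce the tabulated gap", {
  tab <- reference_scatter_fractions()
  gap <- max(abs(tab$sf_measured - tab$sf_simulated))
  expect_equal(gap, 1.5, tolerance = 1e-12)
  expect_equal(tab$setup[which.max(abs(tab$sf_measured - tab$sf_simulated))],
               "CYL")
})
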