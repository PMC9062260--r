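test_that("cold-background NEMA IQ phantom has activity only inside the spheres", {
  sp <- phantom_spec("nema_iq", sphere_concentration = 44.8,
                     background_concentration = 0)
  ph <- build_phantom(sp, voxel = 2)
  expect_true(all(ph$activity >= 0))
  hot <- which(ph$activity > 0, arr.ind = TRUE)
  xs <- ph$origin[1] + (hot[, 1] - 0.5) * ph$voxel[1]
  ys <- ph$origin[2] + (hot[, 2] - 0.5) * ph$voxel[2]
  zs <- ph$origin[3] + (hot[, 3] - 0.5) * ph$voxel[3]
  cen <- petchain:::sphere_centres(sp)
  rad <- sp$sphere_diameters / 2
  dmin <- rep(Inf, nrow(hot))
  for (i in seq_len(nrow(cen))) {
    d <- sqrt((xs - cen[i, 1])^2 + (ys - cen[i, 2])^2 + (zs - cen[i, 3])^2)
    dmin <- pmin(dmin, d - rad[i])
  }
  expect_true(all(dmin <= 0))
  # hot/background ratio of the hot-background configuration
  sp2 <- phantom_spec("nema_iq", sphere_concentration = 32.6,
                      background_concentration = 3.7)
  ph2 <- build_phantom(sp2, voxel = 2)
  expect_equal(max(ph2$activity) / 3.7, 32.6 / 3.7, tolerance = 1e-12)
  expect_equal(max(ph2$activity) / 3.7, 8.81, tolerance = 0.001)
})

test_that("uniform cylinder total activity matches volume x concentration", {
  sp <- phantom_spec("uniform_cylinder", background_concentration = 4.4,
                     radius = 95, length = 200)
  ph <- build_phantom(sp, voxel = 2)
  expected <- 4.4 * pi * 9.5^2 * 20  # kBq
  expect_equal(ph$total_activity_kBq, expected, tolerance = 0.02)
})

test_that("phantom grids are congruent and materials map to attenuation", {
  sp <- phantom_spec("nema_iq", sphere_concentration = 1,
                     background_concentration = 1)
  ph <- build_phantom(sp, voxel = 4)
  expect_identical(dim(ph$activity), dim(ph$mu))
  expect_identical(dim(ph$material), dim(ph$mu))
  expect_true(all(ph$mu >= 0))
  expect_equal(sort(unique(as.numeric(ph$mu))),
               sort(unname(petchain_materials())))
  expect_equal(unname(ph$mu[ph$material == 1L][1]), 0.0958)
  expect_equal(unname(ph$mu[ph$material == 2L][1]), 0.004)
})

test_that("invalid sphere configurations are rejected", {
  sp <- phantom_spec("ds_cylinder", sphere_concentration = 1,
                     sphere_diameters = rep(80, 6))
  expect_error(build_phantom(sp, voxel = 4), "overlap")
  sp2 <- phantom_spec("ds_cylinder", sphere_concentration = 1,
                      sphere_diameters = 130)
  expect_error(build_phantom(sp2, voxel = 4), "outside")
})

test_that("attenuation energy scaling is Compton-dominated and exact at 511 keV", {
  expect_equal(petchain:::mu_energy_scale(511), 1, tolerance = 1e-12)
  e <- c(150, 250, 350, 450, 650)
  k <- petchain:::mu_energy_scale(e)
  expect_true(all(diff(k) < 0))   # decreasing with energy
  # water: mu(200 keV)/mu(511 keV) is about 1.43 (0.137/0.0958)
  expect_equal(petchain:::mu_energy_scale(200), 1.43, tolerance = 0.05)
})
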