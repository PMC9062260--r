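test_that("scanner model enumerates the full crystal set with the stated geometry", {
  expect_equal(nrow(tsc$crystals), 19584)
  expect_equal(tsc$spec$n_rings, 36)
  expect_equal(tsc$spec$n_tax, 544)
  d <- sqrt(tsc$crystals$x^2 + tsc$crystals$y^2)
  expect_equal(min(d), 372.1, tolerance = 1e-12)
  expect_equal(max(d), 372.1, tolerance = 1e-12)
  # rsector 0 centred at 12 o'clock
  r0 <- subset(tsc$crystals, id_rsector == 0 & axial == 0)
  expect_equal(mean(r0$x), 0, tolerance = 1e-9)
  expect_gt(mean(r0$y), 370)
  # z symmetric about the isocenter
  expect_equal(sum(tsc$crystals$z), 0, tolerance = 1e-6)
  expect_error(scanner_spec(n_rsector = 0), "positive")
})

test_that("axial crystal index follows the integer-division arithmetic", {
  expect_equal(axial_crystal_index(0, 0, 0, 0), 0)
  expect_equal(axial_crystal_index(5, 2, 1, 7), 19)
  expect_equal(axial_crystal_index(33, 3, 3, 35), 35)
  expect_error(axial_crystal_index(34, 0, 0, 0), "out of range")
  expect_error(axial_crystal_index(0, 0, 0, 36), "out of range")
})

test_that("transaxial crystal index follows the modulo arithmetic", {
  expect_equal(transaxial_crystal_index(0, 0, 0, 0), 0)
  expect_equal(transaxial_crystal_index(2, 0, 3, 7), 47)
  expect_equal(transaxial_crystal_index(33, 3, 3, 35), 543)
  expect_error(transaxial_crystal_index(-1, 0, 0, 0), "out of range")
})

test_that("crystal address <-> index mapping is a bijection over all crystals", {
  a <- tsc$crystals
  ax <- axial_crystal_index(a$id_rsector, a$id_module, a$id_submodule,
                            a$id_crystal)
  tx <- transaxial_crystal_index(a$id_rsector, a$id_module, a$id_submodule,
                                 a$id_crystal)
  expect_identical(ax, a$axial)
  expect_identical(tx, a$transaxial)
  expect_equal(anyDuplicated(ax * 544 + tx), 0)
  back <- crystal_address_from_index(a$axial, a$transaxial)
  expect_identical(back$id_rsector, a$id_rsector)
  expect_identical(back$id_module, a$id_module)
  expect_identical(back$id_submodule, a$id_submodule)
  expect_identical(back$id_crystal, a$id_crystal)
})

test_that("LOR binning applies the sector and field-of-view cuts", {
  # diametrically opposite crystals, same ring: central radial bin
  b <- lor_to_bin(0, 5, 272, 5, tlay, tsc)
  expect_true(b$accepted)
  expect_true(b$radial %in% c(174, 175))
  # rsector separation below the minimum is rejected
  b2 <- lor_to_bin(8, 0, 2 * 16 + 8, 0, tlay, tsc)
  expect_false(b2$accepted)
})

test_that("binning is symmetric under crystal swap and respects the radial FOV", {
  set.seed(42)
  n <- 1e4
  t1 <- sample(0:543, n, TRUE); r1 <- sample(0:35, n, TRUE)
  t2 <- sample(0:543, n, TRUE); r2 <- sample(0:35, n, TRUE)
  b1 <- lor_to_bin(t1, r1, t2, r2, tlay, tsc)
  b2 <- lor_to_bin(t2, r2, t1, r1, tlay, tsc)
  expect_identical(b1$index, b2$index)
  # analytic closest approach to the axis
  cr <- tsc$crystals[tsc$crystals$axial == 0, ]
  cr <- cr[order(cr$transaxial), ]
  x1 <- cr$x[t1 + 1]; y1 <- cr$y[t1 + 1]
  x2 <- cr$x[t2 + 1]; y2 <- cr$y[t2 + 1]
  cross <- abs(x1 * (y2 - y1) - y1 * (x2 - x1)) /
    sqrt((x2 - x1)^2 + (y2 - y1)^2)
  sec1 <- t1 %/% 16; sec2 <- t2 %/% 16
  dsec <- pmin(abs(sec1 - sec2), 34 - abs(sec1 - sec2))
  ok <- dsec >= 4 & abs(r1 - r2) <= tlay$max_ring_diff
  expect_true(all(cross[b1$accepted] <= 350 + 1e-9))
  expect_true(all(!b1$accepted[ok & cross > 350]))
  expect_true(all(b1$accepted[ok & cross <= 350 - 1e-9]))
})

test_that("histogramming conserves the accepted event count", {
  set.seed(7)
  n <- 5e4
  ev <- data.frame(tax1 = sample(0:543, n, TRUE),
                   ring1 = sample(0:35, n, TRUE),
                   tax2 = sample(0:543, n, TRUE),
                   ring2 = sample(0:35, n, TRUE))
  nb <- bin_events(ev, tlay, tsc)
  expect_equal(sum(nb$array), nb$n_accepted)
  expect_equal(nb$n_accepted + nb$n_rejected, n)
})

test_that("michelogram mode addresses the full span-1 ring-pair set", {
  mlay <- sinogram_layout(tsc, axial_mode = "michelogram")
  expect_equal(mlay$n_planes, 1296)
  b <- lor_to_bin(c(0, 100), c(3, 12), c(272, 400), c(7, 4), mlay, tsc)
  # canonical ordering: smaller ring first
  expect_equal(b$plane, c(3 * 36 + 7, 4 * 36 + 12))
})

test_that("TOF binning negates the offset under crystal swap", {
  tl <- sinogram_layout(tsc, tof_bins = 29L)
  b1 <- lor_to_bin(10, 3, 282, 3, tl, tsc, tof_delta = 300)
  b2 <- lor_to_bin(282, 3, 10, 3, tl, tsc, tof_delta = -300)
  expect_equal(b1$index, b2$index)
  b3 <- lor_to_bin(10, 3, 282, 3, tl, tsc, tof_delta = -300)
  expect_equal(b1$tof + b3$tof, 28)  # mirrored about the central bin
})
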