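# compact layout/grid so the reconstruction tests stay fast
rlay <- sinogram_layout(tsc, n_radial = 64L, n_azimuthal = 32L)
rcfg <- recon_config(image_dim = 48L)

all_bins <- function(layout) {
  nr <- layout$n_radial; na <- layout$n_azimuthal; np <- layout$n_planes
  list(rad = rep(0:(nr - 1), na * np),
       az = rep(rep(0:(na - 1), each = nr), np),
       pl = rep(0:(np - 1), each = nr * na))
}

forward_all <- function(img, layout, cfg) {
  g <- petchain:::image_grid(cfg, layout)
  b <- all_bins(layout)
  ep <- lor_endpoints(b$rad, b$az, b$pl, layout, tsc)
  array(joseph_project(img, ep$p0, ep$p1, g$voxel, g$origin),
        c(layout$n_radial, layout$n_azimuthal, layout$n_planes))
}

smooth_blob <- function(cfg, layout) {
  g <- petchain:::image_grid(cfg, layout)
  xs <- g$origin[1] + (seq_len(g$dims[1]) - 0.5) * g$voxel[1]
  zs <- g$origin[3] + (seq_len(g$dims[3]) - 0.5) * g$voxel[3]
  r2 <- outer(xs^2, xs^2, `+`)
  img <- array(0, g$dims)
  for (k in seq_len(g$dims[3]))
    img[, , k] <- exp(-r2 / (2 * 80^2)) * exp(-zs[k]^2 / (2 * 50^2))
  img
}

test_that("Joseph projection agrees with Siddon on a uniform image", {
  g <- petchain:::image_grid(recon_config(), rlay)  # default fine grid
  img <- array(1, g$dims)
  expect_equal(joseph_project(array(0, g$dims), c(-300, 0, 0),
                              c(300, 0, 0), g$voxel, g$origin), 0)
  set.seed(11)
  n <- 100
  a <- runif(n, 0, pi); s <- runif(n, -250, 250); z <- runif(n, -60, 60)
  P0 <- cbind(-s * sin(a) - 372 * cos(a), s * cos(a) - 372 * sin(a), z)
  P1 <- cbind(-s * sin(a) + 372 * cos(a), s * cos(a) + 372 * sin(a), z)
  jv <- joseph_project(img, P0, P1, g$voxel, g$origin)
  sv <- 10 * siddon_ray_sum(img, P0, P1, g$voxel, g$origin)
  keep <- sv > 100
  expect_lt(max(abs(jv[keep] - sv[keep]) / sv[keep]), 0.01)
})

test_that("forward and back projection are exact adjoints", {
  g <- petchain:::image_grid(rcfg, rlay)
  set.seed(13)
  n <- 300
  P0 <- cbind(runif(n, -350, 350), runif(n, -350, 350), runif(n, -90, 90))
  P1 <- cbind(runif(n, -350, 350), runif(n, -350, 350), runif(n, -90, 90))
  u <- runif(n)
  v <- array(runif(prod(g$dims)), g$dims)
  lhs <- sum(u * joseph_project(v, P0, P1, g$voxel, g$origin))
  rhs <- sum(v * joseph_backproject(u, P0, P1, g$dims, g$voxel, g$origin))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
})

test_that("subset sensitivities are positive in the FOV and sum to the total", {
  s_all <- 0
  for (k in 0:(rcfg$n_subsets - 1))
    s_all <- s_all + sensitivity_image(subset = k, scanner = tsc,
                                       layout = rlay, cfg = rcfg)
  b <- all_bins(rlay)
  ep <- lor_endpoints(b$rad, b$az, b$pl, rlay, tsc)
  g <- petchain:::image_grid(rcfg, rlay)
  full <- joseph_backproject(rep(1, length(b$rad)), ep$p0, ep$p1,
                             g$dims, g$voxel, g$origin)
  expect_equal(s_all, full, tolerance = 1e-10)
  # geometric sensitivity: centre exceeds edge, positive inside the FOV
  mid <- dim(full)[3] %/% 2
  expect_gt(full[24, 24, mid], full[8, 24, mid])
  expect_gt(min(full[20:28, 20:28, mid]), 0)
  # doubling all acf halves the sensitivity
  acf2 <- array(2, c(rlay$n_radial, rlay$n_azimuthal, rlay$n_planes))
  s0 <- sensitivity_image(subset = 0, scanner = tsc, layout = rlay,
                          cfg = rcfg)
  s2 <- sensitivity_image(acf = acf2, subset = 0, scanner = tsc,
                          layout = rlay, cfg = rcfg)
  expect_equal(s2, s0 / 2, tolerance = 1e-12)
})

test_that("OS-EM converges to a consistent solution on noiseless data", {
  x_true <- smooth_blob(rcfg, rlay)
  y <- forward_all(x_true, rlay, rcfg)
  rec <- osem_reconstruct(y, list(), tsc, rlay,
                          recon_config(image_dim = 48L, n_iterations = 20L,
                                       n_subsets = 4L))
  yhat <- forward_all(rec$values, rlay, rcfg)
  expect_lt(sqrt(sum((yhat - y)^2) / sum(y^2)), 0.01)
  expect_true(all(rec$values >= 0))
  # zero prompts drive the image to zero
  rec0 <- osem_reconstruct(0 * y, list(), tsc, rlay,
                           recon_config(image_dim = 48L, n_iterations = 1L))
  expect_equal(max(rec0$values), 0)
  expect_error(osem_reconstruct(y - 10, list(), tsc, rlay, rcfg),
               "negative")
})

test_that("MLEM (one subset) conserves the sensitivity-weighted total", {
  x_true <- smooth_blob(rcfg, rlay)
  y <- forward_all(x_true, rlay, rcfg)
  cfg1 <- recon_config(image_dim = 48L, n_iterations = 1L, n_subsets = 1L)
  cfg2 <- recon_config(image_dim = 48L, n_iterations = 2L, n_subsets = 1L)
  r1 <- osem_reconstruct(y, list(), tsc, rlay, cfg1)
  r2 <- osem_reconstruct(y, list(), tsc, rlay, cfg2)
  sens <- sensitivity_image(subset = 0, scanner = tsc, layout = rlay,
                            cfg = cfg1)
  t1 <- sum(sens * r1$values); t2 <- sum(sens * r2$values)
  expect_lt(abs(t1 - sum(y)) / sum(y), 1e-6)
  expect_lt(abs(t2 - sum(y)) / sum(y), 1e-6)
  # determinism
  r1b <- osem_reconstruct(y, list(), tsc, rlay, cfg1)
  expect_identical(r1$values, r1b$values)
})

test_that("FBP reconstructs a uniform disc and is linear", {
  # analytic disc sinogram: chord length x concentration
  nr <- rlay$n_radial
  s <- -rlay$radial_extent + (seq_len(nr) - 0.5) *
    (2 * rlay$radial_extent / nr)
  chord <- ifelse(abs(s) < 100, 2 * sqrt(pmax(100^2 - s^2, 0)), 0) * 5
  y <- array(0, c(nr, rlay$n_azimuthal, rlay$n_planes))
  y[, , 36] <- chord
  rec <- fbp_initial(y, scanner = tsc, layout = rlay, cfg = rcfg)
  g <- petchain:::image_grid(rcfg, rlay)
  xs <- g$origin[1] + (seq_len(g$dims[1]) - 0.5) * g$voxel[1]
  inside <- outer(xs^2, xs^2, `+`) <= 70^2
  expect_equal(mean(rec$values[, , 36][inside]), 5, tolerance = 0.1)
  expect_lt(max(abs(rec$values[, , 30])), 1e-8)
  rec2 <- fbp_initial(2 * y, scanner = tsc, layout = rlay, cfg = rcfg)
  expect_equal(rec2$values, 2 * rec$values, tolerance = 1e-9)
  expect_equal(max(abs(fbp_initial(0 * y, scanner = tsc, layout = rlay,
                                   cfg = rcfg)$values)), 0)
})

test_that("Gaussian post-filter has the set width and conserves counts", {
  img <- array(0, c(49, 49, 25))
  img[25, 25, 13] <- 1
  voxel <- c(2, 2, 2)
  out <- gaussian_postfilter(img, c(4, 4), voxel = voxel)
  expect_equal(sum(out), 1, tolerance = 1e-6)
  # measured FWHM along x via linear interpolation of half-max crossings
  prof <- out[, 25, 13]
  half <- max(prof) / 2
  xi <- seq_len(49)
  above <- which(prof >= half)
  lo <- min(above); hi <- max(above)
  f1 <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  f2 <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  fwhm_mm <- (f2 - f1) * voxel[1]
  expect_lt(abs(fwhm_mm - 4), 1)   # within half a voxel
  # identity at zero width
  expect_identical(gaussian_postfilter(img, c(0, 0), voxel = voxel), img)
  expect_error(gaussian_postfilter(img, c(-1, 0), voxel = voxel),
               "nonnegative")
})
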