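#' Down-sample a volume onto a coarse grid by cell averaging
#' @keywords internal
resample_mean <- function(arr, voxel, origin, dims_out, voxel_out,
                          origin_out) {
  dm <- dim(arr)
  xs <- origin[1] + (seq_len(dm[1]) - 0.5) * voxel[1]
  ys <- origin[2] + (seq_len(dm[2]) - 0.5) * voxel[2]
  zs <- origin[3] + (seq_len(dm[3]) - 0.5) * voxel[3]
  ix <- floor((xs - origin_out[1]) / voxel_out[1])
  iy <- floor((ys - origin_out[2]) / voxel_out[2])
  iz <- floor((zs - origin_out[3]) / voxel_out[3])
  okx <- ix >= 0 & ix < dims_out[1]
  oky <- iy >= 0 & iy < dims_out[2]
  okz <- iz >= 0 & iz < dims_out[3]
  sub <- arr[okx, oky, okz, drop = FALSE]
  key <- 1 + rep(ix[okx], sum(oky) * sum(okz)) +
    dims_out[1] * (rep(rep(iy[oky], each = sum(okx)), sum(okz)) +
                   dims_out[2] * rep(iz[okz], each = sum(okx) * sum(oky)))
  tot <- rep(0, prod(dims_out)); cnt <- rep(0, prod(dims_out))
  agg <- rowsum(as.numeric(sub), key)
  cntagg <- rowsum(rep(1, length(sub)), key)
  ii <- as.integer(rownames(agg))
  tot[ii] <- agg; cnt[ii] <- cntagg
  array(ifelse(cnt > 0, tot / pmax(cnt, 1), 0), dims_out)
}

coarse_detector <- function(scanner, n_tax_coarse = 68L, n_ax_coarse = 4L) {
  cr <- scanner$crystals[scanner$crystals$axial == 0, ]
  cr <- cr[order(cr$transaxial), ]
  gsize <- scanner$spec$n_tax / n_tax_coarse
  gt <- cr$transaxial %/% gsize
  cx <- rowsum(cr$x, gt) / gsize
  cy <- rowsum(cr$y, gt) / gsize
  rings_per <- scanner$spec$n_rings / n_ax_coarse
  zl <- vapply(0:(n_ax_coarse - 1), function(a)
    mean(crystal_z_r(scanner, (a * rings_per):((a + 1) * rings_per - 1))),
    numeric(1))
  pos <- cbind(x = rep(cx[, 1], n_ax_coarse), y = rep(cy[, 1], n_ax_coarse),
               z = rep(zl, each = n_tax_coarse))
  area <- gsize * scanner$spec$crystal_size[1] *
    rings_per * scanner$spec$crystal_size[2]
  list(pos = pos, tax = rep(0:(n_tax_coarse - 1), n_ax_coarse),
       ax = rep(0:(n_ax_coarse - 1), each = n_tax_coarse),
       area = rep(area, n_tax_coarse * n_ax_coarse),
       n_tax = n_tax_coarse, n_ax = n_ax_coarse,
       sectors_per_tax = scanner$spec$n_rsector / n_tax_coarse)
}

crystal_z_r <- function(scanner, rings) {
  (rings - (scanner$spec$n_rings - 1) / 2) * scanner$geom$zpitch
}

#' Single scatter simulation (SSS)
#'
#' Estimates single-Compton-scatter coincidence rates on a down-sampled
#' detector (68 transaxial x 4 axial crystal groups): the emission and
#' attenuation volumes are down-sampled to a 32 x 32 x 4 grid, scatter
#' points are the coarse voxels with `mu >= mu_threshold` (each jittered
#' uniformly within its voxel, seeded), and for every scatter point and
#' valid coarse crystal pair the two single-scatter terms are evaluated:
#' emitter ray-sums and energy-dependent attenuation ray-sums via Siddon
#' tracing, the scattered energy from the Compton relation at the
#' pair-determined angle, detector efficiencies as the Gaussian-blurred
#' energy-window acceptance (optionally with LYSO stopping), the
#' solid-angle term, and the Klein-Nishina differential cross-section.
#' With `tof = TRUE` each contribution is spread over TOF bins at the
#' arm-length difference convolved with the coincidence timing kernel.
#'
#' @param emission Emission volume: `petchain_recon`, `petchain_phantom`
#'   (activity grid) or array with `voxel`/`origin`.
#' @param mu Attenuation volume (phantom or array), 1/cm at 511 keV.
#' @param scanner,layout Scanner model and target layout.
#' @param cfg Digitizer configuration (energy window/resolution for the
#'   detector efficiency model).
#' @param grid_dim Coarse sampling grid (default `c(32, 32, 4)`).
#' @param mu_threshold Scatter-point threshold, 1/cm.
#' @param tof Produce a TOF-resolved coarse estimate.
#' @param seed Seed of the scatter-point jitter.
#' @param voxel,origin Geometry when arrays are passed (shared by both
#'   volumes, which must be congruent).
#' @return An object of class `petchain_sss`: the coarse sinogram
#'   (`coarse`, dims radial x azimuthal x plane [x tof]) plus the coarse
#'   axes, the scatter points used and the settings.
#' @export
sss_scatter_estimate <- function(emission, mu, scanner, layout,
                                 cfg = digitizer_config(),
                                 grid_dim = c(32L, 32L, 4L),
                                 mu_threshold = 0.04, tof = FALSE,
                                 seed = 1, voxel = NULL, origin = NULL,
                                 n_rad_coarse = 68L) {
  get_grid <- function(x, field) {
    if (inherits(x, "petchain_recon"))
      list(a = x$values, v = x$voxel, o = x$origin)
    else if (inherits(x, "petchain_phantom"))
      list(a = x[[field]], v = x$voxel, o = x$origin)
    else list(a = x, v = voxel, o = origin)
  }
  em <- get_grid(emission, "activity")
  mm <- get_grid(mu, "mu")
  ext <- layout$radial_extent
  zext <- scanner$spec$n_rings * scanner$geom$zpitch
  vout <- c(2 * ext / grid_dim[1], 2 * ext / grid_dim[2], zext / grid_dim[3])
  oout <- c(-ext, -ext, -zext / 2)
  emc <- pmax(resample_mean(em$a, em$v, em$o, grid_dim, vout, oout), 0)
  muc <- pmax(resample_mean(mm$a, mm$v, mm$o, grid_dim, vout, oout), 0)
  sel <- which(muc >= mu_threshold)
  det <- coarse_detector(scanner)
  n_rad_c <- as.integer(n_rad_coarse); n_az_c <- 34L
  n_pl_c <- 2L * det$n_ax - 1L
  tof_bins <- if (tof) layout$tof_bins else 1L
  coarse <- array(0, c(n_rad_c, n_az_c, n_pl_c,
                       max(1L, tof_bins)))
  out <- structure(list(coarse = coarse, n_rad_c = n_rad_c,
                        n_az_c = n_az_c, n_pl_c = n_pl_c,
                        tof = tof, tof_bins = tof_bins,
                        rad_extent = ext, det = det,
                        pair_total = 0,
                        points = matrix(0, 0, 3),
                        grid = list(dim = grid_dim, voxel = vout,
                                    origin = oout, emission = emc, mu = muc)),
                   class = "petchain_sss")
  if (length(sel) == 0 || sum(emc) == 0) return(out)
  set.seed(seed)
  dmx <- grid_dim
  ix <- (sel - 1) %% dmx[1]
  iy <- ((sel - 1) %/% dmx[1]) %% dmx[2]
  iz <- (sel - 1) %/% (dmx[1] * dmx[2])
  pts <- cbind(oout[1] + (ix + stats::runif(length(sel))) * vout[1],
               oout[2] + (iy + stats::runif(length(sel))) * vout[2],
               oout[3] + (iz + stats::runif(length(sel))) * vout[3])
  # valid coarse pairs: sector difference and radial FOV, canonical order
  nc <- nrow(det$pos)
  cmb <- which(upper.tri(matrix(TRUE, nc, nc)), arr.ind = TRUE)
  A <- cmb[, 1]; B <- cmb[, 2]
  sa <- det$tax[A] %/% (det$n_tax / scanner$spec$n_rsector)
  sb <- det$tax[B] %/% (det$n_tax / scanner$spec$n_rsector)
  dsec <- pmin(abs(sa - sb), scanner$spec$n_rsector - abs(sa - sb))
  x1 <- det$pos[A, 1]; y1 <- det$pos[A, 2]
  x2 <- det$pos[B, 1]; y2 <- det$pos[B, 2]
  phi <- atan2(y2 - y1, x2 - x1)
  phi <- ifelse(phi < 0, phi + pi, phi)
  phi <- ifelse(phi >= pi, phi - pi, phi)
  s <- -x1 * sin(phi) + y1 * cos(phi)
  ok <- dsec >= scanner$spec$min_sector_difference & abs(s) <= ext &
    is.finite(phi)
  # canonical order: smaller axial group first, then smaller tax
  swap <- ok & (det$ax[B] < det$ax[A] |
                (det$ax[B] == det$ax[A] & det$tax[B] < det$tax[A]))
  tmp <- A[swap]; A[swap] <- B[swap]; B[swap] <- tmp
  A <- A[ok]; B <- B[ok]; phi <- phi[ok]; s <- s[ok]
  pairs <- cbind(A, B) - 1L
  est <- cpp_sss_core(as.numeric(emc), as.numeric(muc), grid_dim, vout,
                      oout, pts, muc[sel], det$pos, det$area, pairs,
                      cfg$energy_window[1], cfg$energy_window[2],
                      cfg$energy_resolution_fwhm, cfg$crystal_stopping,
                      tof_bins, layout$tof_width, 380)
  irad <- pmin(pmax(floor((s + ext) / (2 * ext) * n_rad_c), 0), n_rad_c - 1)
  iaz <- pmin(floor(phi / pi * n_az_c), n_az_c - 1)
  ipl <- det$ax[A] + det$ax[B]
  key <- 1 + irad + n_rad_c * (iaz + n_az_c * ipl)
  npg <- n_rad_c * n_az_c * n_pl_c
  cntagg <- rowsum(rep(1, length(key)), key)
  filled <- rep(0, npg)
  filled[as.integer(rownames(cntagg))] <- cntagg
  filled <- array(filled > 0, c(n_rad_c, n_az_c, n_pl_c))
  s_ax <- -ext + (seq_len(n_rad_c) - 0.5) * (2 * ext / n_rad_c)
  for (tb in seq_len(max(1L, tof_bins))) {
    agg <- rowsum(est[, tb], key)
    v <- rep(0, npg)
    v[as.integer(rownames(agg))] <- agg / pmax(cntagg, 1)[, 1]
    a3 <- array(v, c(n_rad_c, n_az_c, n_pl_c))
    # radial bins with no coarse LOR: fill by linear interpolation so the
    # spline up-sampling is not pulled to zero
    for (j in seq_len(n_az_c)) for (q in seq_len(n_pl_c)) {
      has <- filled[, j, q]
      if (any(has) && !all(has))
        a3[!has, j, q] <- stats::approx(s_ax[has], a3[has, j, q],
                                        xout = s_ax[!has], rule = 2)$y
    }
    coarse[, , , tb] <- a3
  }
  out$coarse <- coarse
  out$pair_total <- sum(est)
  out$points <- pts
  out
}

spline_matrix <- function(x_in, x_out) {
  sapply(seq_along(x_in), function(i) {
    e <- rep(0, length(x_in)); e[i] <- 1
    stats::spline(x_in, e, xout = x_out, method = "natural")$y
  })
}

linear_periodic_matrix <- function(n_in, n_out, period) {
  xi <- (seq_len(n_in) - 0.5) * period / n_in
  xo <- (seq_len(n_out) - 0.5) * period / n_out
  M <- matrix(0, n_out, n_in)
  for (k in seq_len(n_out)) {
    pos <- xo[k] / (period / n_in) - 0.5
    j0 <- floor(pos); f <- pos - j0
    j0m <- (j0 %% n_in) + 1; j1m <- ((j0 + 1) %% n_in) + 1
    M[k, j0m] <- M[k, j0m] + (1 - f)
    M[k, j1m] <- M[k, j1m] + f
  }
  M
}

#' Up-sample a coarse scatter estimate to the full sinogram size
#'
#' Separable interpolation: natural cubic splines along the radial and
#' axial (plane) directions and periodic linear interpolation along the
#' azimuthal direction; the result is clamped at zero.
#'
#' @param coarse A `petchain_sss` object (or a coarse array with matching
#'   axes taken from `sss`).
#' @param layout Target sinogram layout.
#' @return Scatter sinogram array (radial x azimuthal x plane [x tof]).
#' @export
upsample_scatter <- function(coarse, layout) {
  stopifnot(inherits(coarse, "petchain_sss"))
  ext <- coarse$rad_extent
  s_in <- -ext + (seq_len(coarse$n_rad_c) - 0.5) * (2 * ext / coarse$n_rad_c)
  s_out <- -ext + (seq_len(layout$n_radial) - 0.5) *
    (2 * ext / layout$n_radial)
  # coarse plane centres in fine-plane units
  p_in <- (seq_len(coarse$n_pl_c) - 1) * (layout$n_planes - 1) /
    (coarse$n_pl_c - 1)
  p_out <- seq_len(layout$n_planes) - 1
  Ur <- spline_matrix(s_in, s_out)
  Up <- spline_matrix(p_in, p_out)
  Ua <- linear_periodic_matrix(coarse$n_az_c, layout$n_azimuthal, pi)
  ntof <- dim(coarse$coarse)[4]
  res <- array(0, c(layout$n_radial, layout$n_azimuthal, layout$n_planes,
                    ntof))
  for (tb in seq_len(ntof)) {
    a <- coarse$coarse[, , , tb]
    m1 <- Ur %*% matrix(a, coarse$n_rad_c)               # radial
    a1 <- array(m1, c(layout$n_radial, coarse$n_az_c, coarse$n_pl_c))
    m2 <- Ua %*% matrix(aperm(a1, c(2, 1, 3)), coarse$n_az_c)
    a2 <- aperm(array(m2, c(layout$n_azimuthal, layout$n_radial,
                            coarse$n_pl_c)), c(2, 1, 3))
    m3 <- Up %*% matrix(aperm(a2, c(3, 1, 2)), coarse$n_pl_c)
    a3 <- aperm(array(m3, c(layout$n_planes, layout$n_radial,
                            layout$n_azimuthal)), c(2, 3, 1))
    res[, , , tb] <- pmax(a3, 0)
  }
  if (ntof == 1) array(res[, , , 1], dim(res)[1:3]) else res
}

#' Least-squares scaling of the scatter estimate on the sinogram tails
#'
#' The scatter-only region (tail mask) contains the bins whose
#' forward-projected attenuation line integral is below `mask_threshold`
#' (object-free LORs inside the radial FOV); the up-sampled scatter `s` is
#' scaled to the randoms-subtracted prompts by weighted least squares
#' `sum_b w_b (y_b - s_b beta - q)^2`.  The intercept is forced to zero
#' for isotopes without prompt gamma emission.
#'
#' @param s Scatter sinogram (up-sampled, full size).
#' @param y Prompt sinogram.
#' @param acf Attenuation sinogram defining the tail mask.
#' @param prompt_gamma Fit a free intercept `q` (TRUE) or force `q = 0`.
#' @param randoms Optional randoms sinogram subtracted from `y`.
#' @param support Optional logical/0-1 array of addressable bins.
#' @param mask_threshold Optical-depth threshold for "object-free".
#' @return List with `beta`, `q`, the scaled scatter sinogram `scaled` and
#'   the tail mask.
#' @export
fit_scatter_tails <- function(s, y, acf, prompt_gamma = FALSE,
                              randoms = NULL, support = NULL,
                              mask_threshold = 1e-3) {
  w <- log(acf) < mask_threshold
  if (!is.null(support)) w <- w & support > 0
  if (!any(w)) stop("empty scatter-tail region")
  yy <- if (is.null(randoms)) y else y - randoms
  sv <- s[w]; yv <- yy[w]
  if (prompt_gamma) {
    fit <- stats::lm(yv ~ sv)
    q <- unname(coef(fit)[1]); beta <- unname(coef(fit)[2])
  } else {
    q <- 0
    beta <- sum(sv * yv) / sum(sv * sv)
  }
  if (!is.finite(beta)) beta <- 0
  list(beta = beta, q = q, scaled = pmax(beta * s + q, 0), tail_mask = w)
}

#' Iterative single-scatter estimation
#'
#' Iteration 0 reconstructs the source image with filtered backprojection
#' corrected for randoms, attenuation and normalisation; each iteration
#' re-estimates the scatter (SSS + up-sampling + tail scaling, with the
#' bin-sensitivity pattern eta applied so the estimate lives in prompt
#' counts) and re-reconstructs with OS-EM; after iteration 2 the running
#' estimate is the average of iterations 1 and 2.
#'
#' @param prompts,randoms,acf,eta Sinogram arrays.
#' @param mu Attenuation volume (phantom or array as in
#'   [sss_scatter_estimate()]).
#' @param scanner,layout,cfg,recon_cfg Models and configurations.
#' @param n_iter Number of SSS iterations (default 2).
#' @param tof TOF-resolved estimation.
#' @param seed Scatter-point jitter seed.
#' @param scale Data scale divisor for the reconstructions.
#' @param scatter_pattern Optional bin-sensitivity pattern applied to the
#'   up-sampled estimate (defaults to `eta`; the pipeline passes the
#'   pair-multiplicity pattern).
#' @return List with the final `scatter` sinogram, per-iteration scale
#'   factors `beta`, the per-iteration estimates and the initial image.
#' @export
iterate_sss <- function(prompts, randoms, acf, eta, mu, scanner, layout,
                        cfg = digitizer_config(),
                        recon_cfg = recon_config(), n_iter = 2,
                        tof = FALSE, seed = 1, scale = 1,
                        scatter_pattern = NULL) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  img <- fbp_initial(prompts, randoms = randoms, acf = acf, eta = eta,
                     scanner = scanner, layout = layout, cfg = recon_cfg,
                     scale = scale)
  img$values <- pmax(img$values, 0)
  init_img <- img
  support <- if (is.null(eta)) NULL else eta > 0
  # bin pattern for the up-sampled per-pair scatter rates: the pair
  # multiplicity of the binning (the full normalisation eta additionally
  # carries the trues-specific axial-fan acceptance, which scattered
  # coincidences do not share)
  eta_pat <- if (!is.null(scatter_pattern)) scatter_pattern
             else if (is.null(eta)) 1 else eta
  iters <- list(); betas <- numeric(0)
  running <- NULL
  for (i in seq_len(n_iter)) {
    est <- sss_scatter_estimate(img, mu, scanner, layout, cfg,
                                tof = tof, seed = seed + i)
    up <- upsample_scatter(est, layout) * eta_pat
    fit <- fit_scatter_tails(up, prompts, acf, prompt_gamma = FALSE,
                             randoms = randoms, support = support)
    iters[[i]] <- fit$scaled
    betas <- c(betas, fit$beta)
    running <- if (i == 2) (iters[[1]] + iters[[2]]) / 2 else fit$scaled
    if (i < n_iter) {
      rec <- osem_reconstruct(prompts,
                              list(acf = acf, eta = eta, randoms = randoms,
                                   scatter = running),
                              scanner, layout, recon_cfg, scale = scale)
      img <- rec
    }
  }
  list(scatter = running, beta = betas, iterations = iters,
       initial_image = init_img, last_image = img)
}
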