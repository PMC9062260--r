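#' Reconstruction configuration
#'
#' OS-EM with the Joseph projector: 4 iterations x 16 subsets by default
#' (subsets partition azimuthal views as `view mod n_subsets`), with a
#' separable Gaussian post-filter of 4 mm transaxial and 4 mm axial FWHM.
#' The default image grid is 192 x 192 pixels over the 700 mm transaxial
#' FOV with one slice per sinogram plane.
#'
#' @param n_iterations,n_subsets OS-EM settings.
#' @param image_dim Transaxial matrix size (pixels).
#' @param fov Transaxial field of view, mm.
#' @param postfilter_fwhm mm pair (transaxial, axial).
#' @param epsilon Denominator guard.
#' @return An object of class `petchain_recon_config`.
#' @export
recon_config <- function(n_iterations = 4L, n_subsets = 16L,
                         image_dim = 192L, fov = 700,
                         postfilter_fwhm = c(4, 4), epsilon = 1e-10) {
  structure(list(n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets),
                 projector = "joseph",
                 image_dim = as.integer(image_dim), fov = fov,
                 postfilter_fwhm = postfilter_fwhm,
                 epsilon = epsilon), class = "petchain_recon_config")
}

image_grid <- function(cfg, layout) {
  n <- cfg$image_dim
  vxy <- cfg$fov / n
  if (layout$axial_mode == "ssrb") {
    nz <- layout$n_planes
    vz <- layout$zpitch / 2
  } else {
    nz <- layout$n_rings
    vz <- layout$zpitch
  }
  list(dims = c(n, n, nz), voxel = c(vxy, vxy, vz),
       origin = c(-n * vxy / 2, -n * vxy / 2, -nz * vz / 2))
}

#' Joseph forward projection of arbitrary rays
#'
#' Line integrals (value x mm) sampled at voxel pitch along the dominant
#' axis with bilinear interpolation transversally; [joseph_backproject()]
#' is its exact adjoint.
#'
#' @param image 3-D array.
#' @param p0,p1 n x 3 endpoint matrices, mm.
#' @param voxel,origin Grid geometry.
#' @return Numeric vector of line integrals.
#' @export
joseph_project <- function(image, p0, p1, voxel, origin) {
  p0 <- matrix(p0, ncol = 3); p1 <- matrix(p1, ncol = 3)
  if (any(!is.finite(p0)) || any(!is.finite(p1)))
    stop("ray endpoints must be finite")
  cpp_joseph_fwd(as.numeric(image), dim(image), as.numeric(voxel),
                 as.numeric(origin), p0, p1)
}

#' Adjoint of [joseph_project()]
#'
#' @param values Per-ray values to spread back.
#' @param p0,p1 Ray endpoints.
#' @param dims,voxel,origin Target grid.
#' @return 3-D array.
#' @export
joseph_backproject <- function(values, p0, p1, dims, voxel, origin) {
  p0 <- matrix(p0, ncol = 3); p1 <- matrix(p1, ncol = 3)
  array(cpp_joseph_back(as.numeric(values), as.integer(dims),
                        as.numeric(voxel), as.numeric(origin), p0, p1),
        dims)
}

subset_bins <- function(layout, n_subsets, subset) {
  nr <- layout$n_radial; na <- layout$n_azimuthal; np <- layout$n_planes
  views <- seq(subset, na - 1, by = n_subsets)
  rad <- rep(0:(nr - 1), times = length(views) * np)
  az <- rep(rep(views, each = nr), times = np)
  pl <- rep(0:(np - 1), each = nr * length(views))
  idx <- 1 + rad + nr * (az + na * pl)
  list(rad = rad, az = az, pl = pl, idx = idx)
}

#' Sensitivity image of one OS-EM subset
#'
#' Backprojection of the per-bin system weights `1/(acf x eta)` over the
#' subset's LORs; with the multiplicative corrections in the system matrix
#' this matches the back-projected data term of the OS-EM update.
#'
#' @param acf,eta Correction sinograms (`NULL` = unit).
#' @param subset 0-based subset index.
#' @param scanner,layout Scanner model and layout.
#' @param cfg Reconstruction configuration.
#' @return 3-D sensitivity array.
#' @export
sensitivity_image <- function(acf = NULL, eta = NULL, subset = 0L,
                              scanner, layout, cfg = recon_config()) {
  g <- image_grid(cfg, layout)
  sb <- subset_bins(layout, cfg$n_subsets, subset)
  w <- rep(1, length(sb$idx))
  if (!is.null(acf)) w <- w / acf[sb$idx]
  if (!is.null(eta)) {
    e <- eta[sb$idx]
    w <- ifelse(e > 0, w / e, 0)
  }
  ep <- lor_endpoints(sb$rad, sb$az, sb$pl, layout, scanner)
  joseph_backproject(w, ep$p0, ep$p1, g$dims, g$voxel, g$origin)
}

#' OS-EM reconstruction
#'
#' Multiplicative OS-EM with attenuation and normalisation in the system
#' matrix and additive randoms + scatter in the forward model:
#' `yhat = w A x + r + s` with `w = 1/(acf eta)`.  Nonnegativity is
#' preserved and the result is deterministic for a given subset order.
#'
#' @param prompts Prompt sinogram array.
#' @param corrections List with optional `acf`, `eta`, `randoms`,
#'   `scatter` arrays (bin-congruent with `prompts`).
#' @param scanner,layout Scanner model and layout.
#' @param cfg Reconstruction configuration.
#' @param scale Divide the data by this factor (e.g. duration x
#'   decimation) so image units are acquisition-independent.
#' @return An object of class `petchain_recon`.
#' @export
osem_reconstruct <- function(prompts, corrections = list(), scanner, layout,
                             cfg = recon_config(), scale = 1) {
  if (any(prompts < 0)) stop("negative prompt counts")
  if (length(dim(prompts)) == 4)
    return(osem_reconstruct_tof(prompts, corrections, scanner, layout, cfg,
                                scale))
  g <- image_grid(cfg, layout)
  eps <- cfg$epsilon
  acf <- corrections$acf; eta <- corrections$eta
  add <- NULL
  for (nm in c("randoms", "scatter"))
    if (!is.null(corrections[[nm]])) {
      if (any(corrections[[nm]] < 0)) stop("negative additive correction")
      add <- if (is.null(add)) corrections[[nm]] else add + corrections[[nm]]
    }
  # FOV mask
  xs <- g$origin[1] + (seq_len(g$dims[1]) - 0.5) * g$voxel[1]
  mask2 <- outer(xs^2, xs^2, `+`) <= (cfg$fov / 2)^2
  x <- array(as.numeric(mask2), g$dims)
  # Per-subset data.  The sensitivity uses every addressable ray of the
  # subset; the update pass only needs rays with observed counts (bins
  # with y = 0 contribute an exactly-zero ratio), which makes the cost
  # scale with the recorded counts at sparse desk-scale statistics.
  subsets <- lapply(seq_len(cfg$n_subsets) - 1L, function(k) {
    sb <- subset_bins(layout, cfg$n_subsets, k)
    w <- rep(1, length(sb$idx))
    if (!is.null(acf)) w <- w / acf[sb$idx]
    if (!is.null(eta)) { e <- eta[sb$idx]; w <- ifelse(e > 0, w / e, 0) }
    y <- prompts[sb$idx] / scale
    a <- if (is.null(add)) 0 else add[sb$idx] / scale
    keep_s <- w > 0
    keep_d <- keep_s & y > 0
    list(sens_sb = lapply(sb[c("rad", "az", "pl")], `[`, keep_s),
         sens_w = w[keep_s],
         sb = lapply(sb[c("rad", "az", "pl")], `[`, keep_d),
         w = w[keep_d], y = y[keep_d],
         add = if (length(a) > 1) a[keep_d] else a)
  })
  sens <- lapply(subsets, function(s) {
    ep <- lor_endpoints(s$sens_sb$rad, s$sens_sb$az, s$sens_sb$pl, layout,
                        scanner)
    pmax(as.numeric(joseph_backproject(s$sens_w, ep$p0, ep$p1, g$dims,
                                       g$voxel, g$origin)), eps)
  })
  x <- as.numeric(x)
  for (it in seq_len(cfg$n_iterations)) {
    for (k in seq_along(subsets)) {
      s <- subsets[[k]]
      ep <- lor_endpoints(s$sb$rad, s$sb$az, s$sb$pl, layout, scanner)
      fp <- cpp_joseph_fwd(x, g$dims, g$voxel, g$origin, ep$p0, ep$p1)
      yhat <- s$w * fp + s$add
      ratio <- ifelse(yhat > eps, s$y / yhat, 0)
      bp <- cpp_joseph_back(s$w * ratio, g$dims, g$voxel, g$origin,
                            ep$p0, ep$p1)
      x <- x * (bp / sens[[k]]) * (sens[[k]] > 2 * eps)
    }
  }
  structure(list(values = array(x, g$dims), voxel = g$voxel,
                 origin = g$origin, cfg = cfg, scale = scale),
            class = "petchain_recon")
}

# TOF-weighted OS-EM: prompts (and optionally scatter) carry a TOF axis;
# each TOF bin's forward/back projection weights the Joseph samples with
# the annihilation-localisation kernel (timing resolution + bin width).
# Randoms are uniform over the coincidence window and are spread evenly.
osem_reconstruct_tof <- function(prompts, corrections, scanner, layout,
                                 cfg, scale, timing_fwhm_ps = 380) {
  g <- image_grid(cfg, layout)
  eps <- cfg$epsilon
  ntof <- dim(prompts)[4]
  stopifnot(ntof == layout$tof_bins)
  mm_per_ps <- 0.299792458 / 2
  sigma_mm <- timing_fwhm_ps / 2.3548 * mm_per_ps
  edges_ps <- ((0:ntof) - ntof / 2) * layout$tof_width
  edges_mm <- edges_ps * mm_per_ps
  acf <- corrections$acf; eta <- corrections$eta
  randoms <- corrections$randoms; scatter <- corrections$scatter
  scatter_tof <- !is.null(scatter) && length(dim(scatter)) == 4
  page <- prod(dim(prompts)[1:3])
  xs <- g$origin[1] + (seq_len(g$dims[1]) - 0.5) * g$voxel[1]
  mask2 <- outer(xs^2, xs^2, `+`) <= (cfg$fov / 2)^2
  x <- array(as.numeric(mask2), g$dims)
  # sensitivity over all addressable rays; data passes only over the
  # (ray, TOF bin) pairs with observed counts (zero-count bins give an
  # exactly-zero ratio)
  subsets <- lapply(seq_len(cfg$n_subsets) - 1L, function(k) {
    sb <- subset_bins(layout, cfg$n_subsets, k)
    w <- rep(1, length(sb$idx))
    if (!is.null(acf)) w <- w / acf[sb$idx]
    if (!is.null(eta)) { e <- eta[sb$idx]; w <- ifelse(e > 0, w / e, 0) }
    keep <- w > 0
    sb <- lapply(sb[c("rad", "az", "pl")], `[`, keep)
    idx <- 1 + sb$rad + layout$n_radial *
      (sb$az + layout$n_azimuthal * sb$pl)
    per_t <- lapply(seq_len(ntof), function(t) {
      y_t <- prompts[idx + (t - 1) * page] / scale
      nz <- which(y_t > 0)
      a_t <- if (is.null(randoms)) 0 else randoms[idx[nz]] / (ntof * scale)
      if (!is.null(scatter))
        a_t <- a_t + (if (scatter_tof) scatter[idx[nz] + (t - 1) * page]
                      else scatter[idx[nz]] / ntof) / scale
      list(nz = nz, y = y_t[nz], add = a_t)
    })
    list(sb = sb, w = w[keep], per_t = per_t)
  })
  # flat vectors throughout the update loop to avoid large copies
  sens <- lapply(subsets, function(s) {
    ep <- lor_endpoints(s$sb$rad, s$sb$az, s$sb$pl, layout, scanner)
    pmax(as.numeric(joseph_backproject(s$w, ep$p0, ep$p1, g$dims, g$voxel,
                                       g$origin)), eps)
  })
  x <- as.numeric(x)
  bp <- numeric(prod(g$dims))
  for (it in seq_len(cfg$n_iterations)) {
    for (k in seq_along(subsets)) {
      s <- subsets[[k]]
      bp[] <- 0
      for (t in seq_len(ntof)) {
        pt <- s$per_t[[t]]
        if (length(pt$nz) == 0) next
        ep <- lor_endpoints(s$sb$rad[pt$nz], s$sb$az[pt$nz],
                            s$sb$pl[pt$nz], layout, scanner)
        w_t <- s$w[pt$nz]
        fp <- cpp_joseph_fwd_tof(x, g$dims, g$voxel, g$origin,
                                 ep$p0, ep$p1, edges_mm[t], edges_mm[t + 1],
                                 sigma_mm)
        yhat <- w_t * fp + pt$add
        ratio <- ifelse(yhat > eps, pt$y / yhat, 0)
        bp <- cpp_joseph_back_tof(w_t * ratio, g$dims, g$voxel, g$origin,
                                  ep$p0, ep$p1, edges_mm[t],
                                  edges_mm[t + 1], sigma_mm, bp)
      }
      x <- x * (bp / sens[[k]]) * (sens[[k]] > 2 * eps)
    }
  }
  structure(list(values = array(x, g$dims), voxel = g$voxel,
                 origin = g$origin, cfg = cfg, scale = scale, tof = TRUE),
            class = "petchain_recon")
}

#' @export
print.petchain_recon <- function(x, ...) {
  cat(sprintf("petchain reconstruction: %s voxels of %.2fx%.2fx%.2f mm\n",
              paste(dim(x$values), collapse = "x"),
              x$voxel[1], x$voxel[2], x$voxel[3]))
  cat(sprintf("  value range [%.3g, %.3g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Filtered-backprojection initial image
#'
#' Precorrects the prompts (`(y - randoms) * acf * eta`), ramp-filters each
#' direct plane radially (FFT with zero padding) and backprojects; used to
#' seed the single-scatter simulation.
#'
#' @param prompts Prompt sinogram (SSRB layout).
#' @param randoms,acf,eta Optional correction arrays.
#' @param scanner,layout Scanner model and layout.
#' @param cfg Reconstruction configuration (grid only).
#' @param scale Data scale divisor, as in [osem_reconstruct()].
#' @return A `petchain_recon` object.
#' @export
fbp_initial <- function(prompts, randoms = NULL, acf = NULL, eta = NULL,
                        scanner, layout, cfg = recon_config(), scale = 1) {
  if (layout$axial_mode != "ssrb")
    stop("fbp_initial expects an SSRB layout")
  g <- image_grid(cfg, layout)
  nr <- layout$n_radial; na <- layout$n_azimuthal; np <- layout$n_planes
  ds <- 2 * layout$radial_extent / nr
  nfft <- 2^ceiling(log2(2 * nr))
  kcyc <- c(seq(0, nfft / 2), seq(nfft / 2 - 1, 1)) / nfft
  ramp <- abs(kcyc)[1:nfft]
  out <- array(0, g$dims)
  for (p in seq_len(np)) {
    y <- prompts[, , p] / scale
    if (!is.null(randoms)) y <- y - randoms[, , p] / scale
    if (!is.null(acf)) y <- y * acf[, , p]
    if (!is.null(eta)) {
      e <- eta[, , p]
      y <- ifelse(e > 0, y * e, 0)
    }
    pad <- matrix(0, nfft, na)
    pad[1:nr, ] <- y
    q <- Re(stats::mvfft(stats::mvfft(pad) * ramp, inverse = TRUE)) / nfft
    q <- q[1:nr, , drop = FALSE] / ds
    out[, , p] <- cpp_backproject2d(q, layout$radial_extent,
                                    g$dims[1], g$dims[2],
                                    g$voxel[1], g$voxel[2],
                                    g$origin[1], g$origin[2])
  }
  structure(list(values = out, voxel = g$voxel, origin = g$origin,
                 cfg = cfg, scale = scale), class = "petchain_recon")
}

#' Separable Gaussian post-filter
#'
#' `sigma = fwhm / 2.3548` per axis (transaxial FWHM applied to x and y,
#' axial to z), discretised on the voxel grid with a normalised truncated
#' kernel, so interior totals are conserved; `fwhm = 0` is the identity.
#'
#' @param image A `petchain_recon` object or 3-D array.
#' @param fwhm mm pair (transaxial, axial).
#' @param voxel Voxel size (taken from the recon object if given).
#' @return Same type as `image`.
#' @export
gaussian_postfilter <- function(image, fwhm = c(4, 4), voxel = NULL) {
  obj <- NULL
  if (inherits(image, "petchain_recon")) {
    obj <- image; voxel <- image$voxel; image <- image$values
  }
  if (any(fwhm < 0)) stop("fwhm must be nonnegative")
  dm <- dim(image)
  kern <- function(sig_vox) {
    if (sig_vox <= 0) return(1)
    r <- max(1L, ceiling(4 * sig_vox))
    k <- exp(-((-r:r)^2) / (2 * sig_vox^2))
    k / sum(k)
  }
  conv_axis <- function(arr, k, axis) {
    if (length(k) == 1) return(arr)
    n <- dim(arr)[axis]
    r <- (length(k) - 1) / 2
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok]
    }
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(arr, perm), nrow = n)
    res <- K %*% m
    aperm(array(res, dim(arr)[perm]), order(perm))
  }
  sig <- c(fwhm[1], fwhm[1], fwhm[2]) / 2.3548 / voxel
  out <- image
  for (ax in 1:3) out <- conv_axis(out, kern(sig[ax]), ax)
  if (!is.null(obj)) { obj$values <- out; obj } else out
}
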