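#' Siddon radiological path through a voxel grid
#'
#' Exact sum of `value x intersection length` over the voxels traversed by
#' the segment `p0 -> p1`.  With `vol` holding linear attenuation in 1/cm
#' the result is the dimensionless optical depth.
#'
#' @param vol 3-D array (or a [build_phantom()] object, whose `mu` grid is
#'   used).
#' @param p0,p1 n x 3 endpoint matrices, mm.
#' @param voxel,origin Grid geometry (taken from the phantom if given).
#' @return Numeric vector of line integrals (1/cm x cm).
#' @export
siddon_ray_sum <- function(vol, p0, p1, voxel = NULL, origin = NULL) {
  if (inherits(vol, "petchain_phantom")) {
    voxel <- vol$voxel; origin <- vol$origin; vol <- vol$mu
  }
  p0 <- matrix(p0, ncol = 3); p1 <- matrix(p1, ncol = 3)
  if (any(!is.finite(p0)) || any(!is.finite(p1)))
    stop("ray endpoints must be finite")
  0.1 * cpp_siddon(as.numeric(vol), dim(vol), as.numeric(voxel),
                   as.numeric(origin), p0, p1)
}

#' Attenuation correction factors for every sinogram bin
#'
#' Forward-projects the 511 keV attenuation grid along each bin's
#' geometric ray (endpoints on the crystal front-face cylinder) with the
#' Siddon algorithm and exponentiates: `acf = exp(integral of mu)`, so
#' `acf = 1` where the LOR misses all attenuating material.
#'
#' @param phantom A [build_phantom()] object (its `mu` grid is used).
#' @param scanner,layout Scanner model and sinogram layout.
#' @return Array of attenuation correction factors (>= 1), sinogram dims.
#' @export
attenuation_correction_sinogram <- function(phantom, scanner, layout) {
  nr <- layout$n_radial; na <- layout$n_azimuthal; np <- layout$n_planes
  acf <- array(1, c(nr, na, np))
  rad <- rep(0:(nr - 1), na)
  az <- rep(0:(na - 1), each = nr)
  for (p in 0:(np - 1)) {
    ep <- lor_endpoints(rad, az, rep(p, nr * na), layout, scanner)
    depth <- 0.1 * cpp_siddon(as.numeric(phantom$mu), dim(phantom$mu),
                              phantom$voxel, phantom$origin, ep$p0, ep$p1)
    acf[, , p + 1] <- exp(depth)
  }
  acf
}

#' Randoms sinogram from single rates
#'
#' The expected randoms on a LOR are `R = 2 tau S1 S2 / T`; the sinogram
#' bin value accumulates this over every crystal pair addressing the bin.
#'
#' @param singles_counts Per-crystal singles counts, `n_tax x n_rings`
#'   matrix (as produced by [simulate_acquisition()]).
#' @param duration Acquisition duration T, s.
#' @param two_tau_ns Full coincidence window, ns.
#' @param layout,scanner Layout and scanner model.
#' @return Array of expected random counts per bin.
#' @export
randoms_from_singles <- function(singles_counts, duration, two_tau_ns,
                                 layout, scanner) {
  if (duration <= 0) stop("duration must be positive")
  if (any(singles_counts < 0)) stop("singles counts must be nonnegative")
  r <- cpp_enum_eta(as.numeric(singles_counts),
                    rep(1, scanner$spec$n_rings),
                    scanner$geom, unclass(layout))
  array(r$sum_eb * (two_tau_ns * 1e-9) / duration,
        c(layout$n_radial, layout$n_azimuthal, layout$n_planes))
}

#' Well-counter calibration
#'
#' Converts reconstructed image units to absolute activity concentration:
#' a centred circular ROI is placed in each transverse slice covering the
#' calibration cylinder, and `WCC = C_abs / C_arb` with `C_arb` the mean
#' of the per-slice ROI means.
#'
#' @param image Reconstructed volume (a `petchain_recon` object or a 3-D
#'   array with `voxel`/`origin` supplied).
#' @param known_concentration kBq/mL in the calibration phantom.
#' @param roi_radius ROI radius, mm.
#' @param z_extent Axial range (mm, symmetric about 0) of slices used.
#' @param voxel,origin Grid geometry when `image` is a bare array.
#' @return List with `wcc`, `c_abs`, `c_arb` and the per-slice means.
#' @export
well_counter_calibrate <- function(image, known_concentration,
                                   roi_radius = 70, z_extent = 140,
                                   voxel = NULL, origin = NULL) {
  if (inherits(image, "petchain_recon")) {
    voxel <- image$voxel; origin <- image$origin; image <- image$values
  }
  dm <- dim(image)
  xs <- origin[1] + (seq_len(dm[1]) - 0.5) * voxel[1]
  ys <- origin[2] + (seq_len(dm[2]) - 0.5) * voxel[2]
  zs <- origin[3] + (seq_len(dm[3]) - 0.5) * voxel[3]
  mask <- outer(xs^2, ys^2, `+`) <= roi_radius^2
  sl <- which(abs(zs) <= z_extent / 2)
  per_slice <- vapply(sl, function(k) mean(image[, , k][mask]), numeric(1))
  c_arb <- mean(per_slice)
  if (!is.finite(c_arb) || c_arb == 0)
    stop("well-counter calibration failed: zero mean in the ROI")
  list(wcc = known_concentration / c_arb, c_abs = known_concentration,
       c_arb = c_arb, per_slice = per_slice)
}
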