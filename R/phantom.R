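#' Material table: linear attenuation at 511 keV (1/cm)
#'
#' The energy dependence of all phantom materials is modelled as a common
#' Compton-dominated scaling (Klein-Nishina total cross-section ratio with a
#' small ~E^-3 photoelectric term), applied to the 511 keV values.
#' @param mu_water,mu_lung,mu_plastic 511 keV values, 1/cm.
#' @return Named vector of linear attenuation coefficients.
#' @export
petchain_materials <- function(mu_water = 0.0958, mu_lung = 0.004,
                               mu_plastic = 0.1126) {
  c(air = 0, water = mu_water, lung = mu_lung, plastic = mu_plastic)
}

#' Phantom specification
#'
#' Three analytic phantom families are supported:
#' \describe{
#'   \item{`uniform_cylinder`}{a water cylinder of `radius` x `length` with
#'     uniform activity (`background_concentration`), used for calibration.}
#'   \item{`nema_iq`}{the NEMA IQ body (torso cross-section, 9.7 L, 180 mm
#'     interior length) with six fillable spheres of inner diameters 37, 28,
#'     22, 17, 13, 10 mm on a 57.2 mm-radius ring and an optional central
#'     low-density lung insert (50 mm diameter).}
#'   \item{`ds_cylinder`}{a 110 mm-radius cylindrical phantom (6.7 L) with
#'     six small spheres of inner diameters 15.43, 12.43, 9.89, 6.23, 4.95,
#'     3.95 mm on a 54 mm-radius ring.}
#' }
#' Two additional source-only kinds (`cylinder_source`, `annulus_source`)
#' describe the non-attenuating normalisation-calibration sources.
#'
#' @param kind Phantom family.
#' @param sphere_concentration,background_concentration kBq/mL.
#' @param sphere_diameters mm; defaults depend on `kind`.
#' @param lung_insert Include the lung insert (NEMA IQ only).
#' @param radius,length Cylinder dimensions, mm (cylinder kinds).
#' @param mu_lung Lung-insert linear attenuation at 511 keV, 1/cm.
#' @return An object of class `petchain_phantom_spec`.
#' @export
phantom_spec <- function(kind = c("uniform_cylinder", "nema_iq",
                                  "ds_cylinder", "cylinder_source",
                                  "annulus_source"),
                         sphere_concentration = 0,
                         background_concentration = 0,
                         sphere_diameters = NULL,
                         lung_insert = TRUE,
                         radius = NULL, length = 200,
                         mu_lung = 0.004) {
  kind <- match.arg(kind)
  if (is.null(radius))
    radius <- switch(kind, ds_cylinder = 110, cylinder_source = 100,
                     annulus_source = 355, 95)
  if (is.null(sphere_diameters))
    sphere_diameters <- switch(kind,
      nema_iq = c(37, 28, 22, 17, 13, 10),
      ds_cylinder = c(15.43, 12.43, 9.89, 6.23, 4.95, 3.95),
      numeric(0))
  spec <- list(kind = kind,
               sphere_concentration = sphere_concentration,
               background_concentration = background_concentration,
               sphere_diameters = sphere_diameters,
               lung_insert = lung_insert,
               radius = radius, length = length,
               mu_lung = mu_lung)
  spec$sphere_ring_radius <- switch(kind, nema_iq = 57.2, ds_cylinder = 54, 0)
  spec$body_length <- switch(kind, nema_iq = 180, ds_cylinder = 176, length)
  class(spec) <- "petchain_phantom_spec"
  spec
}

# interior test of the NEMA IQ body cross-section (mm, vectorised)
nema_body_inside <- function(x, y) {
  (y >= 0 & x^2 + y^2 <= 147^2) |
  (y < 0 & abs(x) <= 70 & y >= -77) |
  (y < 0 & abs(x) > 70 & (abs(x) - 70)^2 + y^2 <= 77^2)
}

sphere_centres <- function(spec) {
  n <- length(spec$sphere_diameters)
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0), z = numeric(0)))
  ang <- (seq_len(n) - 1) * 2 * pi / n
  cbind(x = spec$sphere_ring_radius * cos(ang),
        y = spec$sphere_ring_radius * sin(ang),
        z = rep(0, n))
}

#' Rasterise a phantom specification onto a voxel grid
#'
#' Voxels are classified by their centre position (no partial-volume
#' weighting).  The returned object pairs the activity grid (kBq/mL) with
#' the 511 keV linear-attenuation grid (1/cm) and a material label grid.
#'
#' @param spec A [phantom_spec()].
#' @param voxel Isotropic voxel size, mm.
#' @param margin Grid margin beyond the phantom, mm.
#' @param materials 511 keV attenuation table from [petchain_materials()].
#' @return An object of class `petchain_phantom` with `activity`, `mu`,
#'   `material`, `voxel` (mm triple), `origin` (grid corner, mm) and
#'   `total_activity_kBq`.
#' @export
build_phantom <- function(spec, voxel = 2, margin = 10,
                          materials = petchain_materials(mu_lung = spec$mu_lung)) {
  half_xy <- switch(spec$kind,
    nema_iq = 150, ds_cylinder = spec$radius,
    annulus_source = spec$radius + 3, spec$radius) + margin
  half_z <- spec$body_length / 2 + margin
  nx <- ny <- 2L * as.integer(ceiling(half_xy / voxel))
  nz <- 2L * as.integer(ceiling(half_z / voxel))
  ox <- -nx / 2 * voxel; oz <- -nz / 2 * voxel
  xs <- ox + (seq_len(nx) - 0.5) * voxel
  zs <- oz + (seq_len(nz) - 0.5) * voxel
  X <- matrix(xs, nx, ny)
  Y <- matrix(xs, nx, ny, byrow = TRUE)
  R2 <- X^2 + Y^2
  inside_xy <- switch(spec$kind,
    nema_iq = nema_body_inside(X, Y),
    ds_cylinder = R2 <= spec$radius^2,
    uniform_cylinder = R2 <= spec$radius^2,
    cylinder_source = R2 <= spec$radius^2,
    annulus_source = R2 <= (spec$radius + 2)^2 & R2 >= spec$radius^2)
  zin <- abs(zs) <= spec$body_length / 2
  attenuating <- spec$kind %in% c("nema_iq", "ds_cylinder", "uniform_cylinder")
  # acrylic shell (~3 mm wall + end plates) around the attenuating phantoms
  wall <- 3
  wall_xy <- switch(spec$kind,
    nema_iq = nema_body_inside(X / (1 + wall / 150), Y / (1 + wall / 150)) &
      !inside_xy,
    ds_cylinder = ,
    uniform_cylinder = R2 <= (spec$radius + wall)^2 & !inside_xy,
    array(FALSE, dim(X)))
  cap_xy <- inside_xy | wall_xy
  material <- array(0L, c(nx, ny, nz))
  activity <- array(0, c(nx, ny, nz))
  bg <- spec$background_concentration
  for (k in which(zin)) {
    m <- ifelse(inside_xy, if (attenuating) 1L else 0L, 0L)
    if (attenuating) m[wall_xy] <- 3L
    material[, , k] <- m
    activity[, , k] <- ifelse(inside_xy, bg, 0)
  }
  if (attenuating) {
    kcap <- which(!zin & abs(zs) <= spec$body_length / 2 + wall)
    for (k in kcap) {
      m <- material[, , k]; m[cap_xy] <- 3L; material[, , k] <- m
    }
  }
  if (spec$kind == "nema_iq" && spec$lung_insert) {
    lung_xy <- R2 <= 25^2
    for (k in which(zin)) {
      m <- material[, , k]; a <- activity[, , k]
      m[lung_xy] <- 2L; a[lung_xy] <- 0
      material[, , k] <- m; activity[, , k] <- a
    }
  }
  cen <- sphere_centres(spec)
  if (nrow(cen) > 0) {
    rad <- spec$sphere_diameters / 2
    # configuration checks: inside the body, pairwise disjoint
    if (nrow(cen) > 1) {
      dd <- as.matrix(stats::dist(cen))
      diag(dd) <- Inf
      if (any(dd < outer(rad, rad, `+`)))
        stop("sphere configuration error: spheres overlap")
    }
    for (i in seq_len(nrow(cen))) {
      ok_xy <- switch(spec$kind,
        nema_iq = all(nema_body_inside(cen[i, 1] + c(-1, 1) * rad[i],
                                       cen[i, 2] + c(-1, 1) * rad[i])),
        sqrt(sum(cen[i, 1:2]^2)) + rad[i] <= spec$radius)
      if (!isTRUE(ok_xy)) stop("sphere configuration error: outside body")
      kz <- which(abs(zs - cen[i, 3]) <= rad[i])
      for (k in kz) {
        d2 <- (X - cen[i, 1])^2 + (Y - cen[i, 2])^2
        inside <- d2 <= rad[i]^2 - (zs[k] - cen[i, 3])^2
        a <- activity[, , k]
        a[inside] <- spec$sphere_concentration
        activity[, , k] <- a
      }
    }
  }
  mu <- array(materials[material + 1L], dim(material))
  voxvol_mL <- voxel^3 / 1000
  out <- list(spec = spec, activity = activity, mu = mu, material = material,
              voxel = rep(voxel, 3), origin = c(ox, ox, oz),
              materials = materials,
              total_activity_kBq = sum(activity) * voxvol_mL)
  class(out) <- "petchain_phantom"
  out
}

#' Energy scaling of water-like linear attenuation
#'
#' Ratio mu(E)/mu(511 keV) used across the transport and scatter models:
#' Klein-Nishina total cross-section scaling plus a small E^-3
#' photoelectric component.
#'
#' @param energy keV (vectorised).
#' @return Dimensionless scale factors.
#' @keywords internal
mu_energy_scale <- function(energy) {
  skn <- function(E) {
    a <- E / 511
    l <- log(1 + 2 * a)
    (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - l / a) +
      l / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2
  }
  fpe <- 1.5e-4
  r <- 511 / energy
  (1 - fpe) * skn(energy) / skn(511) + fpe * r^3
}
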