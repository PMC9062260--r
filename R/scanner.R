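#' Scanner specification for a Discovery-MI-like cylindrical PET system
#'
#' Describes the nested detector hierarchy used by the simulator and the
#' sinogram binner: 34 rsectors arranged on a ring, each holding 4 axial
#' modules of 4 transaxial submodules, each submodule a 4 (transaxial) x 9
#' (axial) LYSO crystal array -- 19584 crystals in total, 36 rings of 544
#' crystals.  The transaxial crystal pitch is 3.95 mm and the axial pitch
#' 5.3 mm (36 rings span the nominal 20 cm axial field of view); crystals
#' are 25 mm deep and their front faces sit at a radius of 372.1 mm
#' (744.2 mm face-to-face).
#'
#' @param n_rsector,n_module_axial,n_module_transaxial Detector multiplicities.
#' @param n_submodule_transaxial,n_submodule_axial Submodules per module.
#' @param n_crystal_transaxial,n_crystal_axial Crystals per submodule.
#' @param crystal_size `c(transaxial, axial, depth)` in mm.
#' @param face_to_face_diameter Crystal front-face diameter, mm.
#' @param transaxial_fov Transaxial field of view diameter, mm.
#' @param min_sector_difference Minimum rsector separation for a coincidence.
#' @param bore_liner `list(radius, thickness)` of the plastic bore liner, mm.
#' @return An object of class `petchain_scanner_spec`.
#' @export
scanner_spec <- function(n_rsector = 34L,
                         n_module_axial = 4L,
                         n_module_transaxial = 1L,
                         n_submodule_transaxial = 4L,
                         n_submodule_axial = 1L,
                         n_crystal_transaxial = 4L,
                         n_crystal_axial = 9L,
                         crystal_size = c(3.95, 5.3, 25),
                         face_to_face_diameter = 744.2,
                         transaxial_fov = 700,
                         min_sector_difference = 4L,
                         bore_liner = list(radius = 350, thickness = 2)) {
  spec <- list(
    n_rsector = as.integer(n_rsector),
    n_module_axial = as.integer(n_module_axial),
    n_module_transaxial = as.integer(n_module_transaxial),
    n_submodule_transaxial = as.integer(n_submodule_transaxial),
    n_submodule_axial = as.integer(n_submodule_axial),
    n_crystal_transaxial = as.integer(n_crystal_transaxial),
    n_crystal_axial = as.integer(n_crystal_axial),
    crystal_size = crystal_size,
    face_to_face_diameter = face_to_face_diameter,
    transaxial_fov = transaxial_fov,
    min_sector_difference = as.integer(min_sector_difference),
    bore_liner = bore_liner)
  mult <- unlist(spec[1:7])
  if (any(mult <= 0) || any(crystal_size <= 0) || face_to_face_diameter <= 0)
    stop("scanner specification fields must be positive")
  spec$n_rings <- spec$n_module_axial * spec$n_submodule_axial *
    spec$n_crystal_axial
  spec$n_tax <- spec$n_rsector * spec$n_module_transaxial *
    spec$n_submodule_transaxial * spec$n_crystal_transaxial
  spec$n_crystals <- spec$n_rings * spec$n_tax
  class(spec) <- "petchain_scanner_spec"
  spec
}

#' Build the scanner model: crystal centres, normals and index tables
#'
#' rsector 0 is centred at 12 o'clock (+y) seen from the front of the
#' gantry, with rsector numbers increasing clockwise; the coordinate system
#' is right-handed with z along the bore and the origin at the isocenter.
#' Crystal front-face centres lie on the 372.1 mm radius cylinder; the
#' transaxial crystals of one rsector form a contiguous arc (angular pitch
#' = transaxial crystal size / radius) with gaps between rsectors.
#'
#' @param spec A [scanner_spec()].
#' @return An object of class `petchain_scanner` with elements `spec`,
#'   `geom` (flat geometry list used by the compiled kernels) and
#'   `crystals` (one row per crystal: address, axial/transaxial index,
#'   centre coordinates in mm).
#' @export
build_scanner <- function(spec = scanner_spec()) {
  n_tax_sector <- spec$n_module_transaxial * spec$n_submodule_transaxial *
    spec$n_crystal_transaxial
  if (spec$n_tax != spec$n_rsector * n_tax_sector)
    stop("inconsistent transaxial multiplicities")
  radius <- spec$face_to_face_diameter / 2
  geom <- list(
    n_sector = spec$n_rsector,
    n_tax_sector = as.integer(n_tax_sector),
    n_rings = as.integer(spec$n_rings),
    radius = radius,
    dalpha = spec$crystal_size[1] / radius,
    zpitch = spec$crystal_size[2],
    min_sector_diff = spec$min_sector_difference)
  tax <- 0:(spec$n_tax - 1)
  sec <- tax %/% n_tax_sector
  tin <- tax %% n_tax_sector
  alpha <- sec * (2 * pi / spec$n_rsector) +
    (tin - (n_tax_sector - 1) / 2) * geom$dalpha
  theta <- pi / 2 - alpha
  ring <- 0:(spec$n_rings - 1)
  zc <- (ring - (spec$n_rings - 1) / 2) * geom$zpitch
  crystals <- data.frame(
    axial = rep(ring, each = spec$n_tax),
    transaxial = rep(tax, spec$n_rings),
    x = rep(radius * cos(theta), spec$n_rings),
    y = rep(radius * sin(theta), spec$n_rings),
    z = rep(zc, each = spec$n_tax))
  addr <- crystal_address_from_index(crystals$axial, crystals$transaxial, spec)
  crystals <- cbind(addr, crystals)
  out <- list(spec = spec, geom = geom, crystals = crystals)
  class(out) <- "petchain_scanner"
  out
}

#' @export
print.petchain_scanner <- function(x, ...) {
  s <- x$spec
  cat("petchain scanner model\n")
  cat(sprintf("  %d crystals: %d rings x %d crystals/ring\n",
              s$n_crystals, s$n_rings, s$n_tax))
  cat(sprintf("  front-face radius %.1f mm, axial extent %.1f mm\n",
              x$geom$radius, s$n_rings * x$geom$zpitch))
  cat(sprintf("  min sector difference %d, transaxial FOV %.0f mm\n",
              s$min_sector_difference, s$transaxial_fov))
  invisible(x)
}

check_address <- function(id_rsector, id_module, id_submodule, id_crystal,
                          spec) {
  n_mod <- spec$n_module_axial * spec$n_module_transaxial
  n_smod <- spec$n_submodule_axial * spec$n_submodule_transaxial
  n_cry <- spec$n_crystal_axial * spec$n_crystal_transaxial
  if (any(id_rsector < 0 | id_rsector >= spec$n_rsector) ||
      any(id_module < 0 | id_module >= n_mod) ||
      any(id_submodule < 0 | id_submodule >= n_smod) ||
      any(id_crystal < 0 | id_crystal >= n_cry))
    stop("crystal address id out of range")
}

#' Axial (ring) index of a crystal from its Gate-style volume-ID address
#'
#' Integer-division arithmetic over the nested (rsector, module, submodule,
#' crystal) hierarchy; crystal ids inside a submodule are ordered
#' transaxial-fastest, so `id_crystal %/% n_crystal_transaxial` is the
#' crystal's axial position in its block.
#'
#' @param id_rsector,id_module,id_submodule,id_crystal Zero-based ids
#'   (vectorised).
#' @param spec A [scanner_spec()].
#' @return Integer ring indices in `[0, n_rings - 1]`.
#' @export
axial_crystal_index <- function(id_rsector, id_module, id_submodule,
                                id_crystal, spec = scanner_spec()) {
  check_address(id_rsector, id_module, id_submodule, id_crystal, spec)
  (id_rsector %/% spec$n_rsector) *
    (spec$n_module_axial * spec$n_submodule_axial * spec$n_crystal_axial) +
  (id_module %/% spec$n_module_transaxial) *
    (spec$n_submodule_axial * spec$n_crystal_axial) +
  (id_submodule %/% spec$n_submodule_transaxial) * spec$n_crystal_axial +
  id_crystal %/% spec$n_crystal_transaxial
}

#' Transaxial (in-ring) index of a crystal from its address
#'
#' @inheritParams axial_crystal_index
#' @return Integer in-ring indices in `[0, crystals_per_ring - 1]`.
#' @export
transaxial_crystal_index <- function(id_rsector, id_module, id_submodule,
                                     id_crystal, spec = scanner_spec()) {
  check_address(id_rsector, id_module, id_submodule, id_crystal, spec)
  n_cry_smod_tax <- spec$n_crystal_transaxial
  n_cry_mod_tax <- spec$n_submodule_transaxial * n_cry_smod_tax
  n_cry_rsec_tax <- spec$n_module_transaxial * n_cry_mod_tax
  id_crystal %% spec$n_crystal_transaxial +
    n_cry_smod_tax * (id_submodule %% spec$n_submodule_transaxial) +
    n_cry_mod_tax * (id_module %% spec$n_module_transaxial) +
    n_cry_rsec_tax * id_rsector
}

#' Invert the (axial, transaxial) crystal indexing back to an address
#'
#' @param axial,transaxial Zero-based ring and in-ring indices (vectorised).
#' @param spec A [scanner_spec()].
#' @return A data.frame with columns `id_rsector`, `id_module`,
#'   `id_submodule`, `id_crystal`.
#' @export
crystal_address_from_index <- function(axial, transaxial,
                                       spec = scanner_spec()) {
  if (any(axial < 0 | axial >= spec$n_rings) ||
      any(transaxial < 0 | transaxial >= spec$n_tax))
    stop("crystal index out of range")
  n_tax_sector <- spec$n_module_transaxial * spec$n_submodule_transaxial *
    spec$n_crystal_transaxial
  n_ax_module <- spec$n_submodule_axial * spec$n_crystal_axial
  id_rsector <- transaxial %/% n_tax_sector
  tin <- transaxial %% n_tax_sector
  smod_tax <- tin %/% spec$n_crystal_transaxial
  cry_tax <- tin %% spec$n_crystal_transaxial
  mod_ax <- axial %/% n_ax_module
  ax_in_mod <- axial %% n_ax_module
  smod_ax <- ax_in_mod %/% spec$n_crystal_axial
  cry_ax <- ax_in_mod %% spec$n_crystal_axial
  data.frame(
    id_rsector = id_rsector,
    id_module = mod_ax * spec$n_module_transaxial,  # transaxial part is 0
    id_submodule = smod_ax * spec$n_submodule_transaxial + smod_tax,
    id_crystal = cry_ax * spec$n_crystal_transaxial + cry_tax)
}

#' Sinogram layout
#'
#' Bin addressing for the LOR histograms.  Radial bins are uniform in the
#' signed closest-approach distance of the LOR to the scanner axis over
#' `±radial_extent`; azimuthal bins are uniform in the LOR direction
#' angle over `[0, pi)`; the axial coordinate is either the full span-1
#' Michelogram (`"michelogram"`, `n_rings^2` ring pairs with the
#' smaller-ring-first canonical ordering) or single-slice-rebinned direct
#' planes (`"ssrb"`, plane index = ring1 + ring2, `2 n_rings - 1` planes).
#' An optional TOF axis of `tof_bins` bins of `tof_width` ps covers the
#' coincidence window symmetrically.
#'
#' @param scanner A [build_scanner()] model.
#' @param n_radial Number of radial bins (default 350, i.e. 2 mm bins).
#' @param n_azimuthal Number of azimuthal views (crystals-per-ring / 2).
#' @param axial_mode `"ssrb"` or `"michelogram"`.
#' @param tof_bins Number of TOF bins (1 = non-TOF).
#' @param tof_width TOF bin width, ps.
#' @param radial_extent Maximum LOR closest-approach distance, mm.
#' @return An object of class `petchain_layout`.
#' @export
sinogram_layout <- function(scanner = build_scanner(),
                            n_radial = 350L,
                            n_azimuthal = scanner$spec$n_tax %/% 2L,
                            axial_mode = c("ssrb", "michelogram"),
                            tof_bins = 1L, tof_width = 169,
                            radial_extent = scanner$spec$transaxial_fov / 2,
                            max_ring_diff = NULL) {
  axial_mode <- match.arg(axial_mode)
  nr <- scanner$spec$n_rings
  n_planes <- if (axial_mode == "ssrb") 2L * nr - 1L else nr * nr
  # SSRB assigns oblique LORs to their mean plane; a ring-difference cap
  # bounds the axial mispositioning of off-axis sources
  if (is.null(max_ring_diff))
    max_ring_diff <- if (axial_mode == "ssrb") 11L else nr - 1L
  l <- list(
    n_radial = as.integer(n_radial),
    n_azimuthal = as.integer(n_azimuthal),
    n_planes = as.integer(n_planes),
    mode = if (axial_mode == "ssrb") 0L else 1L,
    axial_mode = axial_mode,
    tof_bins = as.integer(tof_bins),
    tof_width = tof_width,
    radial_extent = radial_extent,
    max_ring_diff = as.integer(max_ring_diff),
    zpitch = scanner$geom$zpitch,
    n_rings = nr,
    version = "petchain-sino-2")
  class(l) <- "petchain_layout"
  l
}

layout_dims <- function(layout) {
  d <- c(layout$n_radial, layout$n_azimuthal, layout$n_planes)
  if (layout$tof_bins > 1L) d <- c(d, layout$tof_bins)
  d
}

#' Map LOR crystal-index pairs to sinogram bins
#'
#' Applies the minimum-sector-difference and radial field-of-view cuts and
#' returns the bin coordinates; swapping the two crystals of a LOR yields
#' the same non-TOF bin (the TOF offset changes sign with the canonical
#' crystal ordering).
#'
#' @param transaxial1,axial1,transaxial2,axial2 Crystal indices (vectorised).
#' @param layout A [sinogram_layout()].
#' @param scanner The scanner model.
#' @param tof_delta Optional TOF differences `t1 - t2` in ps.
#' @return A data.frame with `accepted`, 0-based `radial`, `azimuthal`,
#'   `plane`, `tof` bin coordinates and the 1-based linear `index`.
#' @export
lor_to_bin <- function(transaxial1, axial1, transaxial2, axial2,
                       layout, scanner, tof_delta = NULL) {
  n <- length(transaxial1)
  td <- if (is.null(tof_delta)) numeric(0) else as.numeric(tof_delta)
  idx0 <- cpp_lor_bin(as.integer(transaxial1), as.integer(axial1),
                      as.integer(transaxial2), as.integer(axial2),
                      td, scanner$geom, unclass(layout))
  nr <- layout$n_radial; na <- layout$n_azimuthal; np <- layout$n_planes
  page <- as.double(nr) * na * np
  i <- as.double(idx0)
  tof <- i %/% page
  rem <- i %% page
  plane <- rem %/% (as.double(nr) * na)
  rem2 <- rem %% (as.double(nr) * na)
  data.frame(accepted = !is.na(idx0),
             radial = rem2 %% nr,
             azimuthal = rem2 %/% nr,
             plane = plane,
             tof = tof,
             index = i + 1)
}

#' Histogram a coincidence event list into a sinogram
#'
#' @param events Data frame with columns `tax1`, `ring1`, `tax2`, `ring2`
#'   and optionally `tof_delta_ps` (from [sort_coincidences()] or
#'   [simulate_acquisition()]).
#' @param layout,scanner Layout and scanner model.
#' @return A list with the sinogram `array` (dims radial x azimuthal x
#'   plane [x tof]) and the accepted/rejected counts.
#' @export
bin_events <- function(events, layout, scanner, integer_counts = FALSE) {
  td <- if (layout$tof_bins > 1L && !is.null(events$tof_delta_ps))
    as.numeric(events$tof_delta_ps) else numeric(0)
  r <- cpp_bin_events(as.integer(events$tax1), as.integer(events$ring1),
                      as.integer(events$tax2), as.integer(events$ring2),
                      td, scanner$geom, unclass(layout), integer_counts)
  sino <- r$sino
  dim(sino) <- layout_dims(layout)
  list(array = sino, n_accepted = r$n_accepted, n_rejected = r$n_rejected)
}

#' Geometric ray endpoints of sinogram bins
#'
#' For SSRB layouts the ray lies in the plane's mean-z slice; for
#' Michelogram layouts the endpoints take the two ring z positions.  The
#' endpoints sit on the crystal front-face cylinder.
#'
#' @param radial,azimuthal,plane 0-based bin coordinates (vectorised).
#' @param layout,scanner Layout and scanner model.
#' @return A list of two n x 3 matrices `p0`, `p1` (mm).
#' @export
lor_endpoints <- function(radial, azimuthal, plane, layout, scanner) {
  R <- scanner$geom$radius
  ext <- layout$radial_extent
  s <- -ext + (radial + 0.5) * (2 * ext / layout$n_radial)
  phi <- (azimuthal + 0.5) * (pi / layout$n_azimuthal)
  half <- sqrt(pmax(R^2 - s^2, 0))
  cx <- -s * sin(phi); cy <- s * cos(phi)
  ux <- cos(phi); uy <- sin(phi)
  nr <- layout$n_rings
  zmid <- (nr - 1) / 2
  if (layout$axial_mode == "ssrb") {
    z0 <- z1 <- (plane / 2 - zmid) * layout$zpitch
  } else {
    r1 <- plane %/% nr; r2 <- plane %% nr
    z0 <- (r1 - zmid) * layout$zpitch
    z1 <- (r2 - zmid) * layout$zpitch
  }
  list(p0 = cbind(cx - half * ux, cy - half * uy, z0),
       p1 = cbind(cx + half * ux, cy + half * uy, z1))
}
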