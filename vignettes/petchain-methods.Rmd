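---
title: "petchain: models, corrections and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petchain: models, corrections and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

petchain is a desk-scale computational chain for quantitative PET: a Monte
Carlo simulator of a Discovery-MI-like time-of-flight scanner, the
quantitative correction chain (attenuation, component-based normalisation,
singles-based randoms, iterative single scatter simulation, well-counter
calibration), OS-EM reconstruction and NEMA NU 2-2007-style image-quality
evaluation.  This vignette records the models behind each stage, the
parameters that matter, and the design decisions taken where the design was
genuinely open.

## Scanner model

The scanner is a cylindrical LYSO system: 34 rsectors on a 744.2 mm
face-to-face ring, each with 4 axial modules of 4 transaxial submodules
holding 4 x 9 (transaxial x axial) crystals -- 19584 crystals in 36 rings of
544.  Crystal pitch is 3.95 mm transaxially and 5.3 mm axially (36 rings
span the nominal 20 cm axial field of view), with 25 mm crystal depth.  The
widely quoted crystal dimensions are ambiguous about which side is
transaxial; 544 x 5.3 mm would exceed the ring circumference (2338 mm), so
the 3.95 mm side must be transaxial.  rsector 0 is centred at 12 o'clock and
numbering increases clockwise seen from the front; the crystals of one
rsector form a contiguous arc, with small gaps between rsectors.

Crystal addresses follow the Gate-style nested volume IDs, and the
axial/transaxial crystal indices are computed with the standard
integer-division/modulo arithmetic over the hierarchy (tested as an exact
bijection over all 19584 crystals).  Crystal ids inside a submodule are
ordered transaxial-fastest, which is forced by the axial index using
`id_crystal %/% 4`.

## Sinogram layout

The proprietary sinogram organisation of the real scanner is not public, so
the layout here is an open stand-in: 350 radial bins uniform in the signed
closest-approach distance over +-350 mm (2 mm bins, about half the crystal
pitch, i.e. interleaved sampling), 272 azimuthal views (crystals-per-ring /
2) uniform in the LOR angle, and either the full span-1 Michelogram (36^2
ring pairs, used for structural tests) or single-slice rebinning (SSRB, 71
direct planes at 2.65 mm spacing), which is what the shipped pipeline uses.
An optional TOF axis covers the +-2.45 ns coincidence window.

SSRB assigns an oblique LOR to the plane at the mean of its two ring
positions, which mispositions off-axis activity axially by up to
`rho * tan(theta)`.  With the full span-1 set this reaches ~14 mm for the
sphere ring of the image-quality phantom and visibly destroys small-sphere
contrast, so the default layout caps the ring difference at 11 (axial
mispositioning below ~2.5 mm at 57 mm off-axis, retaining about half the
coincidences).  This cap is a desk-scale compromise: the reference system
reconstructs the full 3-D data set.

## Simulator

The simulator replaces a full Monte Carlo particle-transport code with a
simplified annihilation-photon model whose every component is testable
against closed forms:

* Decays are Poisson with mean `activity x duration x 0.967` (the F-18
  beta-plus yield), positions sampled from the activity grid through a
  Walker alias table with uniform jitter inside the voxel, photon pairs
  back-to-back (optional Gaussian acollinearity, off by default; positron
  range is omitted -- both are small against the 3.95 mm crystal pitch and
  4 mm post-filter).
* Photon transport is Woodcock delta-tracking over the attenuation grid.
  All phantom materials share a Compton-dominated energy scaling of the
  511 keV attenuation (Klein-Nishina cross-section ratio plus a small E^-3
  photoelectric term); scattering angles are rejection-sampled from the
  Klein-Nishina differential cross-section and energies follow the Compton
  relation.  Photons below 250 keV are terminated (the energy window starts
  at 425 keV).  Transport matches `exp(-mu L)` transmission and the
  numerically integrated Klein-Nishina distribution within statistics.
* Detection projects the photon onto the 372.1 mm crystal cylinder; the
  bore liner (2 mm plastic at 350 mm) attenuates, and photons falling in
  inter-rsector gaps or outside the axial extent are lost.  An
  energy-dependent LYSO interaction probability `1 - exp(-mu_LYSO(E) x
  25 mm)` is applied so that down-scattered photons are not under-detected
  relative to 511 keV ones.
* The digitizer chain mirrors a Gate-style front end: per-decay adder and
  rsector-level energy-winner readout (imitating Compton scatter recovery),
  a flat detection efficiency (0.98), Gaussian energy blur (9.63% FWHM at
  511 keV scaling as 1/sqrt(E)), the 425-650 keV discriminator, Gaussian
  timing blur (268.7 ps FWHM per single, giving the 380 ps coincidence
  timing resolution), and a multi-window coincidence sorter with
  takeAllGoods and minimum rsector difference 4 (total window 4.9 ns).
* The Lu-176 intrinsic background is a Poisson stream (1142 kHz before the
  window) uniform over crystals; its deposited-energy spectrum is a
  documented approximation (beta continuum with endpoint 593 keV plus
  partial absorption of the 88/202/307 keV cascade gammas), as the exact
  spectrum of the reference chain is not published.

Ground-truth labels (true / scattered / random, Lu-176 involvement, object
scatter counts) ride along every prompt, which the tests use as an oracle.

What the simulator does **not** emulate, and what passing tests therefore do
not show about real data: deadtime and pile-up (deliberately absent),
detector-side Compton scatter between rsectors (lost or mispositioned events
on a real system; its omission lowers the simulated scatter fraction a few
percentage points relative to a full Monte Carlo), Rayleigh scattering,
bore-liner and couch scatter (the liner only attenuates), and
depth-of-interaction parallax.

## Correction chain

**Attenuation.** Exact Siddon radiological paths from the 511 keV
attenuation grid along each bin's geometric ray; `acf = exp(integral)`.

**Component-based normalisation.** Two non-attenuating calibration sources
are simulated: a central uniform cylinder (radius 100 mm, axial FOV long)
for the crystal efficiencies and axial factors, and a thin annulus shell at
355 mm -- outside the transaxial FOV -- for the radial and crystal
interference factors.  Crystal efficiencies come from fan sums with the
sector-averaged geometric fan profile (within-rsector position x ring)
divided out, normalised per ring; the axial block profile `b` is the per-ring deviation from the
smoothed ring profile; the axial geometric factor `g` is the per-plane
observed/expected ratio; the radial profile `r` and the interference factor
`f` (view phase within the 8-view rsector period x radial bin) come from
the annulus after crystal/axial correction.  The per-bin normalisation
`eta` multiplies the pair-aggregated crystal term (which also carries the
deterministic pair multiplicity of the binning) with `g`, `r` and `f`.
With 1e7 coincidences the per-crystal fan counts are ~1000, so the
efficiency estimate carries ~3% Poisson noise against the ~5% efficiency
spreads of interest, and the recovery correlation for a planted 5%
(relative) spread rises only slowly with calibration size (about 0.78 at
1.2e8 decays and 0.92 at 5e8 in our recovery experiments; the Poisson fan
noise plus a small count-independent floor put r = 0.95 near 8e8 decays,
beyond the test suite's practical run time).  Note that planted
efficiencies are survival probabilities: values above 1/0.98 saturate
against the flat detection efficiency, so recovery experiments centre the
plant below 1.

**Randoms.** `R = 2 tau S1 S2 / T` accumulated over every crystal pair of
each bin, from the measured per-crystal singles counts.

**Single scatter simulation.** Emission and attenuation volumes are
down-sampled to 32 x 32 x 4; scatter points are the coarse voxels with
`mu >= 0.04 1/cm`, each jittered uniformly within its voxel (seeded); the
detector is down-sampled to 68 transaxial x 4 axial groups.  For every
scatter point and valid coarse pair both single-scatter terms are evaluated
(emitter and attenuation ray sums, Compton-relation energy, Klein-Nishina
differential cross-section, solid angle with front-face obliquity).  The
detector efficiency at energy E -- not defined by the reference chain -- is
modelled as the Gaussian-blurred window acceptance times the LYSO stopping
probability, the single largest modelling choice in this module.  The
coarse pair estimates are averaged into a coarse sinogram of 68 radial x
34 azimuthal x 7 plane bins (matching the natural radial density of the
coarse detector; radial bins without a coarse LOR are filled by linear
interpolation -- coarser radial binning was found to smear the object
edge into the tail region and bias the tail fit low), up-sampled with
natural cubic splines (radial, axial) and periodic linear interpolation
(azimuthal), multiplied by the bin-sensitivity pattern `eta`, and scaled
to the randoms-subtracted prompts
by least squares over the scatter-only tail region (bins whose attenuation
line integral is below 1e-3); the intercept is fixed at 0 for isotopes
without prompt gamma emission.  The procedure runs iteratively: iteration 0
seeds the source image with FBP (randoms/attenuation/normalisation
corrected), each iteration re-estimates and re-reconstructs, and the
estimate after iteration 2 is the average of iterations 1 and 2.  The
FBP-seeded first estimate is noticeably low at desk-scale counts, so the
pipeline default runs a third iteration (reconstructed with the averaged
estimate) and returns its scale-fitted result; the scatter-fraction
estimate converges by then.
Multiple scatter is not modelled; the tail scaling compensates for it
only partially, which together with the simulator's deliberately absent
detector-side scatter leaves the estimated scatter fraction a few
percentage points below both the ground-truth labels and the reference
values, and sets a floor on the residual lung error.

**Well-counter calibration.** A uniform cylinder of known concentration is
taken through the full chain; `WCC = C_abs / C_arb` with `C_arb` the mean
of per-slice centred ROI means.  Because the reconstruction divides the
data by `duration x decimation`, the factor transfers between acquisitions
with different scales.

## Reconstruction

OS-EM with 4 iterations x 16 subsets (azimuthal views modulo 16, fixed
order) and the Joseph projector (voxel-pitch sampling along the dominant
axis, bilinear transversally; forward and back projection are exact
adjoints).  The forward model is `yhat = w A x + r + s` with
`w = 1/(acf eta)`: multiplicative corrections live in the system matrix and
in the per-subset sensitivity image, additive randoms and scatter in the
denominator.  A 1e-10 denominator guard protects bins outside the support;
iterates stay nonnegative, and with one subset each full iteration
preserves the sensitivity-weighted image total.  Reconstruction is
deterministic.  The default image grid is 192 x 192 pixels over the 700 mm
FOV (3.65 mm) with one slice per SSRB plane (2.65 mm); the reference
reconstructions do not state a matrix, and 192 matches clinical practice
for this bore.  The reconstructed point-source FWHM on this grid is ~3 mm
before filtering; images are post-filtered with a separable Gaussian of
4 mm transaxial and 4 mm axial FWHM.

Time-of-flight reconstruction weights each sample of the Joseph ray with
the probability that the annihilation position falls in the event's TOF
bin (Gaussian kernel from the 380 ps coincidence resolution combined with
the bin width).  The shipped pipeline reconstructs the final image with 9
TOF bins of 545 ps; the scatter-estimation loop stays non-TOF.  TOF mainly
matters for cold-region convergence: at 4 x 16 the residual lung error of
the cold insert is convergence-limited without TOF.

The FBP initialiser (scatter-estimation seed only) single-slice-rebins,
ramp-filters radially (FFT with 2x zero padding) and backprojects
pixel-driven per plane.

## Evaluation

NEMA NU 2-2007-style metrics: scatter fraction `S/(T+S)` with trues
estimated as prompts minus estimated randoms and scatter; per-sphere CRC
`(S_i/B_i - 1)/(a_H/a_B - 1)`, SNR `(S_i - B_i)/sigma_i` and background
variability `SD/mean` of the 60 background ROI means.  Sixty background
ROIs = 12 transaxial positions x 5 slices (0, +-10, +-20 mm).  The 12
positions are fixed package constants chosen to keep 15 mm clearance (at
the largest ROI size) from the phantom wall, every sphere and the lung
insert: 8 on a 112 mm arc over the top half plus 4 lateral-inferior
positions for the torso-shaped phantom, and a 80 mm ring at 30-degree
offsets for the small-sphere cylinder.  `sigma_i` pools all voxels of the
60 ROIs.  The residual lung error averages `C_lung/B_37` over the 60
central slices with a 30 mm ROI on the insert.  Line profiles sample
trilinearly.

## Desk-scale study sizes

The reference acquisitions are 10-minute frames at full clinical
activities (~1e10 decays, ~1e8-1e9 prompts).  The package reproduces the
protocol at the same durations and concentrations but with the activity
decimated: the acceptance analysis runs the NEMA IQ hot-background frame
at decimation 4.5e-3 (~9e7 decays, ~1.5e6 prompts) and the small-sphere
cylinder frame at 4e-3, with the normalisation calibrations at 1.2e8
decays per source; the test suite uses slightly smaller runs of the same
design (down to decimation 2e-3).  At these sizes the contrast-recovery
estimates of the largest sphere carry a few percentage points of counting
noise and those of the smallest spheres considerably more; counts-scaled
statistics (SNR, background variability) do not transfer from decimated
runs at all and are validated only at the formula level.

## Known limitations

* Scatter-fraction estimates inherit both the missing multiple-scatter
  model (shared with the reference implementation) and the simulator's
  missing detector-side scatter, so the estimated SF sits several
  percentage points below the reference values.
* SSRB with a ring-difference cap discards about half the counts and
  retains a small axial blur; the reference system reconstructs fully 3-D
  data.
* The normalisation components are estimated from a finite calibration run
  and carry Poisson noise into `eta`; at the shipped calibration sizes
  this is negligible against the prompt-count noise.
* Absolute image units are arbitrary until well-counter calibration; all
  shipped metrics are ratios and do not depend on it.
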