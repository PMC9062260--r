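# petchain

A desk-scale computational chain for quantitative PET, from Monte Carlo
simulation to NEMA image-quality metrics, written for medical-imaging
physicists who want to study how acquisition and correction choices
propagate into reconstructed images.

The package models a Discovery-MI-like cylindrical time-of-flight scanner
(34 rsectors x 4 x 4 blocks of 4 x 9 LYSO crystals; 19584 crystals in 36
rings; 744.2 mm face-to-face; 425-650 keV window; 380 ps coincidence
timing) and implements, as one tested toolkit:

* a **simulator**: annihilation-photon transport through voxel phantoms
  (Woodcock delta-tracking, Klein-Nishina Compton sampling), a Gate-style
  digitizer chain (rsector-level adder + energy-winner readout, energy and
  timing blur, Lu-176 intrinsic background, multi-window takeAllGoods
  coincidence sorting) with per-prompt ground-truth labels;
* **sinogram binning**: crystal-index arithmetic over the nested detector
  hierarchy, Michelogram or single-slice-rebinned layouts, optional TOF
  axis;
* the **correction chain**: Siddon attenuation factors, component-based
  normalisation estimated from simulated cylinder + annulus calibration
  sources, singles-based randoms (`R = 2 tau S1 S2 / T`), iterative
  single scatter simulation (SSS) with cubic-spline up-sampling and
  least-squares tail scaling, and well-counter calibration;
* **reconstruction**: OS-EM (4 iterations x 16 subsets) with the Joseph
  projector, attenuation/normalisation in the system matrix, additive
  randoms + scatter, optional TOF weighting, FBP seeding for the scatter
  loop, and a 4 mm Gaussian post-filter;
* **evaluation**: NEMA NU 2-2007-style scatter fraction, contrast
  recovery (CRC), SNR, background variability, residual lung error and
  line profiles with automatic ROI placement.

The statistics behind the metrics, in the field's notation:
`SF = S/(T+S)`, `CRC_i = (S_i/B_i - 1)/(a_H/a_B - 1)`,
`SNR_i = (S_i - B_i)/sigma_i`, `BV_i = SD(B_i)/mean(B_i)`,
`dC = C_lung/B_37`, with `eta = eps_u eps_v b_u b_v g r f` for the
normalisation components and `acf = exp(integral of mu)` for attenuation.

## Worked example

A decimated NEMA IQ hot-background frame (spheres 32.6 kBq/mL over a
3.7 kBq/mL background, 10-minute frame at 0.3% of the clinical activity),
through the full chain:

```r
library(petchain)
scanner <- build_scanner()
cfg <- pipeline_config(
  phantom = list(kind = "nema_iq", sphere_concentration = 32.6,
                 background_concentration = 3.7),
  duration = 600, decimation = 3e-3, seed = 7)
res <- run_pipeline(cfg, scanner)
print(res$report)
```

which prints (seed 7; the run simulates 6.3e7 decays into 1.03e6 prompts
and takes roughly ten minutes on one CPU):

```
NEMA image-quality report (nema_iq, SBR 8.81)
   37.00 mm sphere: CRC  81.3 %  SNR   4.49  BV  17.9 %
   28.00 mm sphere: CRC  57.3 %  SNR   3.14  BV  26.0 %
   22.00 mm sphere: CRC  56.6 %  SNR   3.09  BV  35.1 %
   17.00 mm sphere: CRC  68.0 %  SNR   3.71  BV  43.6 %
   13.00 mm sphere: CRC  27.0 %  SNR   1.55  BV  51.2 %
   10.00 mm sphere: CRC  53.9 %  SNR   3.10  BV  58.3 %
  residual lung error: 19.2 %
```

CRC is the fraction of the true 8.81:1 sphere-to-background contrast
recovered in the image; it falls with sphere size because of the ~5 mm
reconstructed resolution, and at this decimation the small-sphere values
carry tens of percentage points of counting noise (the 17 mm sphere
exceeding the 22 mm one here is noise, not physics).  The residual lung
error measures how much apparent activity the correction chain leaves in
the cold lung insert; its level here reflects the known single-scatter
underestimate and the 4 x 16 cold-region convergence discussed in the
methods vignette.  SNR and background variability scale with the
simulated counts and do not transfer to clinical statistics.
`res$sf_estimated` is the scatter fraction from the estimation chain
(28.6% in this run) and `res$sf_truth` the one from the simulator's
ground-truth labels (32.2%).

A thin command-line wrapper is installed with the package
(`inst/cli/petchain`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli/petchain", package="petchain"))') \
    all --config nema.yaml --seed 7 --out out/
```

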