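# dacshift

Per-pixel spectral response correction (DAC-shifting) for
photon-counting CT, with signal-to-thickness calibration, filtered
backprojection, spectral Hounsfield calibration, and the image-quality
statistics needed to compare correction strategies — plus a synthetic
spectral CT simulator that exercises the whole pipeline end to end.

## The problem

Photon-counting detectors (Medipix-class chips and relatives) set their
energy thresholds per chip as integer DAC (digital-to-analogue
converter) units. The DAC-to-keV map is close to linear per chip, but
each *pixel* realises a slightly different keV value for the same
setting — threshold dispersion. A nominally uniform flat field is
therefore noisy across pixels, and because the error is fixed per
detector element, it reconstructs into concentric ring artefacts in CT.
Standard flat-field correction does not remove it: the error is
energy-dependent, so it reappears as soon as the beam spectrum changes
inside an object (beam hardening).

DAC-shifting corrects the projection data directly, using only
flat-field images taken with the scan:

1. Per threshold, the median count over all pixels is taken as the
   ideal target count.
2. Each pixel's count response across the acquired DAC settings is
   modelled with a cubic spline, and the fractional DAC at which the
   pixel's response equals the target is solved for — yielding a
   per-pixel, per-threshold look-up table (LUT) of corrected DAC
   positions.
3. Every projection is resampled per pixel through a spline fitted to
   its own threshold series, evaluated at the LUT positions, so all
   pixels reflect the same keV thresholds. Flat-field correction then
   divides by the ideal targets.

Everything is done separately per counter, since the response is
counter-specific. Because the flats are acquired with the scan, the
method is robust against detector drift — unlike per-pixel
signal-to-thickness calibration (STC-P), which silently degrades when
the response changes between calibration and scan. The package
implements both (and detector-wide STC-D, which linearises beam
hardening: normalised counts q(t) measured through stepped absorber
thicknesses are interpolated and inverted to equivalent thickness), so
the strategies can be compared quantitatively.

Reconstructions are calibrated per threshold to spectral Hounsfield
units via

    HU(E) = 1000 * (mu(E) - mu_water(E)) / (mu_water(E) - mu_air(E))

which pins the water ROI median to 0 HU and the air ROI median to
-1000 HU at every threshold energy E. Precision is quantified by the
*percentile size* (width of the central 95% band of a homogeneous ROI),
options are ranked by the *effectiveness score* (mean paired relative
change in percentile size, with IQR and paired t-test), ring structure
by a radial-profile variance metric, and K-edge contrast quantification
by through-origin regression (y = m·x) with Fisher r-to-z comparison of
correlations.

## Worked example

```r
library(dacshift)

spectrum <- source_spectrum(kvp = 50, filtration_mm_al = 0.5)
detector <- detector_model(chips = c(1, 2), chip_pixels = c(1, 64),
                           pitch_mm = 0.2, sigma_dac = 8, seed = 42)
plan <- default_plan(n_angles = 180, angle_step_deg = 1)

# model the pixel responses from flat fields and build the LUT
flats <- simulate_flat_stack(detector, spectrum, plan, n_frames = 10, seed = 1)
targets <- compute_target_counts(flats)
lut <- build_lut(fit_flat_splines(flats, detector), targets)
lut
#> <response_lut> 10 thresholds x 1x128 pixels
#>   entries: interpolated = 1022, extrapolated = 256, failed = 2

flat <- flats[[1]]
corrected <- correct_frame(flat, lut)
# 14 keV flat: inter-pixel CoV 14.9% -> 0.61% after DAC-shifting
```

The dispersion (`sigma_dac = 8` DAC units, about 1.6 keV here) inflates
the inter-pixel coefficient of variation of a flat field to ~15%;
DAC-shifting brings it down to the Poisson floor. End to end, on the
default 20 mm insert phantom:

```r
scan <- simulate_scan(detector, spectrum, plan, default_phantom(), seed = 7)
rois <- phantom_rois(default_phantom(), n = 128, voxel_mm = 0.2)
ootb <- evaluate_arm(process_scan(scan, "OOTB"), rois)
dac  <- evaluate_arm(process_scan(scan, "DAC"),  rois)
sel <- ootb$summary$kev %in% c(9, 11, 14, 17, 20, 25)   # interior thresholds
effectiveness_score(ootb$summary$mean_percentile_size[sel],
                    dac$summary$mean_percentile_size[sel])
#> <effectiveness_result> -91.1% (IQR -95.2%: -91.8%), t = -4.87, p = 0.0046 * (n = 6)
```

Negative scores are improvements: here DAC-shifting shrinks the mean
95%-band width of homogeneous materials by ~91% relative to plain
flat-field correction, and `dac$rings` shows the ring metric dropping
by 1-2 orders of magnitude at interior thresholds.

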