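---
title: "Correcting per-pixel threshold dispersion in spectral photon-counting CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting per-pixel threshold dispersion in spectral photon-counting CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dacshift)
```

## The measurement model

A photon-counting pixel registers a photon when its deposited charge
exceeds a comparator threshold, programmed per chip in integer DAC
units. Per chip and counter the DAC-to-keV relation is affine,
`E = s·d + b`, calibrated from X-ray fluorescence points
(`fit_dac_to_kev()`, unweighted least squares — the calibration sources
give no uncertainty to weight by). The per-pixel deviation from this
chip-level map is modelled as a pure DAC offset `delta` per pixel and
counter: a pixel with offset `delta` programmed to DAC `d` behaves as
an ideal pixel at `d - delta`, i.e. its effective threshold is
`s·(d - delta) + b`. No per-pixel gain term is modelled; the look-up
table produced by the correction stores exactly one corrected DAC per
pixel and threshold, which is the quantity a pure offset model
predicts. Offsets are drawn i.i.d. normal with standard deviation
`sigma_dac` (default 8 DAC units ≈ 1.6 keV at the default calibration
of 0.2 keV/DAC — chosen so that the 95% range of per-pixel DACs at a
14 keV threshold spans ≈ 32 DAC units, the magnitude a Medipix3-class
system exhibits).

The source is a Kramers-type bremsstrahlung spectrum,
`S(E) ∝ (kVp − E)/E`, filtered by an effective attenuation
`mu_f(E) = 300/E^3 + 0.04` (1/mm) for the 0.5 mm aluminium filter.
The photoelectric coefficient is deliberately softer than bulk
aluminium: it is an *effective* beam-plus-detector-response model,
calibrated so that exposure-balanced open-beam counts across the
default threshold ladder (5–25 keV) reproduce the relative exposure
times of the reference acquisition protocol (2.08 / 2.88 / 4.48 /
9.60 / 9.60 s). A bulk-aluminium coefficient would leave essentially no
flux below 9 keV, whereas real systems of this class count usefully at
a 5 keV threshold because the detector's spectral response (charge
sharing, fluorescence escape) redistributes counts downward — physics
that is intentionally not modelled here. Materials use a two-term
attenuation model `mu(E) = p/E^3 + c` with plausible diagnostic-energy
magnitudes (water ≈ 0.037/mm at 30 keV); iodine solutions add a
concentration-proportional term whose photoelectric part jumps by a
factor 5.4 at 33.2 keV.

Expected counts are
`exposure × ∫_thr^kVp S(E)·exp(-Σ mu_i(E)·t_i) dE`, evaluated by
trapezoid quadrature on a 0.5 keV grid with linear interpolation at the
threshold; Poisson sampling sits on top. The geometry is 2-D
parallel-beam with analytic chord lengths through cylindrical phantoms
— one detector row, which preserves every per-column effect that
matters for ring artefacts while keeping reconstruction desk-scale.
Detector quantum efficiency is taken as unity (no sensor absorption
model). Random detector motion draws an integer shift uniformly in
±5 pixels per projection and records it losslessly in the frame
metadata.

## DAC-shifting

`compute_target_counts()` takes, per threshold, the median count over
all flat frames and pixels as the ideal homogeneous flat-field value.
`fit_flat_splines()` models each pixel's response across that counter's
DAC positions; `build_lut()` solves `response(d) = target` per pixel
and threshold by bracketed root finding; `correct_frame()` fits a
spline through each pixel's projection counts and evaluates it at the
LUT positions; `ideal_ffc()` divides by the targets. Counters never
mix.

Numerical choices worth recording:

* **Count-rate axis.** Adjacent thresholds are acquired with different
  exposure times, so raw counts versus DAC is not monotone (the
  exposure steps dominate). All response modelling and resampling is
  done in counts per second and rescaled to each threshold's exposure
  afterwards; this leaves every contract unchanged while making the
  curve single-valued.
* **Log-rate splines.** The open-beam response is near-exponential in
  DAC. Both the LUT root finding and the projection resampling fit the
  spline to the log count rate (floored at a tiny rate so empty
  thresholds stay evaluable), which roughly halves the interpolation
  error between knots and makes the correction of the flats themselves
  reproduce the targets to machine precision.
* **Spline order.** Interpolating natural cubic splines by default
  (`order = 3`); a quadratic least-squares variant (`order = 2`) is
  selectable. With five samples per counter, interpolation (no
  smoothing) is used — noise regularisation comes from the median over
  repeat flats.
* **Extrapolation.** Roots are searched up to 20% of the DAC span
  beyond the sampled range and flagged `extrapolated`; this mirrors the
  known inaccuracy of the edge thresholds, roughly half of whose pixels
  genuinely need extrapolation. Pixels with no root are flagged
  `failed` and their corrected counts filled with the median of the
  8-neighbourhood; edge thresholds should not be over-interpreted.
* **Fractional DACs.** LUT entries are real-valued; rounding would
  quantise the correction to whole DAC steps (≈ 0.2 keV).
* **Flat pooling.** Pre- and post-scan flat stacks are pooled before
  the median; with a stable source this only improves the target
  estimate.

## Signal-to-thickness calibration

`stc_normalize()` divides per-thickness median counts by the
thickness-0 median, so q(0) = 1 exactly. The default curve model is a
monotone cubic interpolation of effective optical depth `-log q`
versus thickness (isotonic projection first so noisy per-pixel series
stay invertible), inverted in closed form through the spline. A
three-parameter rational curve `q(t) = (1 + a·t)/(1 + b·t + c·t^2)`
(a, b, c ≥ 0, q(0) = 1 identically) is available via
`form = "hyperbola"`; it captures the overall beam-hardening curvature
but cannot linearise the heavily hardened lowest thresholds to the 1%
level the interpolating form achieves, which is why the latter is the
default. STC-D fits the detector medians once per threshold; STC-P
fits every pixel. Out-of-range values clamp: q ≥ 1 to thickness 0,
values below the calibrated range to 1.1 × the maximum calibrated
thickness (the data do not constrain thickness beyond that).

## Reconstruction and calibration

Sinograms are assembled from one detector row with recorded motion
shifts undone by integer back-shifts (columns shifted outside the
detector are filled with the open-beam value). Filtered backprojection
uses the spatial-domain ramp kernel (so the DC term is exact) with
cosine apodisation by default; Ram-Lak and Hann are selectable. HU
calibration is affine per threshold from the water and air ROI
medians, which therefore sit at exactly 0 and -1000 HU by
construction — this is an anchor of the method, not an empirical
outcome, and the test suite asserts it to machine precision.

## Evaluation statistics

The "95th percentile range" is interpreted as the central band between
the 2.5th and 97.5th empirical percentiles (the band's endpoints are
otherwise unspecified); its width is the percentile size. Effectiveness
scores pair mean-percentile-sizes per (configuration × interior
threshold), report the mean and (P25, P75) of the paired relative
changes, and a paired t-test with significance at p < 0.01. For the
drift comparison, "unchanged within its IQR" is operationalised as
overlapping (P25, P75) intervals of the matched and drifted per-pair
changes. The Fisher r-to-z comparison takes n as the number of
regression points. The ring metric — variance of the radial mean
profile in a homogeneous annulus over its squared mean — is a
convenience diagnostic for ring structure, not a published statistic.

In the 2-D K-edge experiment the attenuation-above-threshold profile is
a cumulative quantity: the steep rise caused by the edge *completes* at
the first threshold at or above the edge energy, so the edge estimate
is the upper threshold of the maximal upward finite difference.
Threshold dispersion smears the mean profile and drags the steepest
rise ~1.5 keV below the edge; the experiment therefore applies
DAC-shifting (the flat acquisition doubles as the LUT source, as in the
real protocol) before profiling. The default fluence gives ≈ 2.4
million open-beam counts over the 48 s exposure so that Poisson noise
does not flip the maximal jump between neighbouring 0.5 keV intervals.

## Problem sizes and what the tests show

The shipped scenes use one detector row of 128 pixels (two 64-pixel
chips), 120–180 projection angles, and 128² reconstructions; flat-field
studies use up to 64×64 pixels. These sizes are large enough for the
corrected-versus-uncorrected contrasts to be decisive (percentile sizes
separate by factors of 5–20, ring metrics by 1–2 orders of magnitude)
while keeping the full suite around two minutes.

The simulator emulates threshold dispersion, beam hardening, Poisson
noise, detector motion and response drift. It does **not** emulate
charge sharing, pulse pile-up, sensor polarisation, scatter, cone-beam
geometry, or spatially structured (non-i.i.d.) offset maps. Passing
tests therefore demonstrate that the implementation corrects what the
offset model produces — they do not certify performance on real
detector data, where part of the dispersion is not a pure threshold
offset. The correction requires multi-threshold data by construction:
a single-threshold acquisition gives the spline nothing to resample.

## Known limitations

* Edge thresholds (first and last per counter) rely on extrapolated
  roots and are systematically less accurate; quantitative claims are
  restricted to interior thresholds throughout.
* The B-spline response model is purely empirical; a physics-informed
  response function with uncertainty weighting would extrapolate
  better.
* STC assumes the calibration material dominates the beam-hardening
  path; objects of very different composition linearise imperfectly.
* The 2-D parallel-beam geometry cannot reproduce cone-beam-specific
  artefacts; the correction itself is geometry-agnostic.
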