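---
title: "Monitoring incipient biofouling on RO membranes: methods and design"
author: "biofoulr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring incipient biofouling on RO membranes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofoulr)
```

## The monitoring problem

Biofouling — microbial attachment followed by biofilm growth in the
spacer-filled feed channel of a reverse-osmosis (RO) module — degrades
permeability and raises the feed-channel pressure drop (FCP), but those
classical online indicators respond only after the biofilm is well
established. Two much earlier signals are available in a lab-scale flat
module:

* **time-lapse photographs** of the membrane surface, in which a growing
  biofilm shifts the scene from white to brown, and
* **polymer-optical-fiber (POF) transmission**: the light carried by a
  decladded fiber laid in the feed channel is attenuated as deposits
  accumulate on its sensing zone.

`biofoulr` implements the computational side of this monitoring scheme:
registration of the image series, a per-colour-layer similarity indicator,
the process formulas (carbon mass balance and permeability), and automated
onset/plateau/cleaning-recovery calls — together with a synthetic-scenario
simulator that generates image, fiber and process series with the
statistical structure the detectors assume, so the entire pipeline is
testable without a pilot plant.

## Image registration

Module vibration and motor motion shift the camera slightly between
exposures, so frames must be aligned before pixelwise comparison. The
motion model is a pure integer translation, estimated by template matching:

1. the user selects a distinctive rectangular feature region (typically a
   piece of the spacer mesh) on the grayscale reference frame
   (`template_roi()`, `extract_template()`);
2. `ncc_map()` scores every fully interior placement of the template on the
   sensed grayscale frame with the normalized cross-correlation, i.e. the
   Pearson coefficient between the template and the image window under it;
3. `locate_peak()` takes the arg-max (ties broken by smallest row, then
   smallest column — a deterministic convention);
4. `register_frame()` crops margins `(Mr, Mc)` from the colour frame,
   shifting the crop by the estimated offset so the feature region occupies
   identical coordinates in every output frame.

Grayscale conversion uses the ITU-R BT.601 luma weights
`(0.2989, 0.5870, 0.1140)/255`; parameters are estimated on the grayscale
pair and applied to the colour frame.

Numerical design:

* The sliding NCC is evaluated with a summed-area table for the window
  means/variances and an FFT cross-correlation for the numerator. This is
  algebraically identical to the direct per-window Pearson computation; the
  test suite checks agreement with a brute-force double loop to better
  than 1e-8 (observed ~1e-14).
* Only *valid* placements (template fully inside the image) are scored;
  zero-padded border scores are never produced, so no border artifact can
  win the peak search.
* Windows whose variance is at summation round-off level are scored `NA`
  and excluded from the peak: a featureless window is not evidence.
* With the default margins `(127, 175)` a 2064 x 3088 frame registers to
  1937 x 2913. The crop anchor for zero offset is `floor(margin/2)`
  (63, 87), which splits the room for movement as evenly as an odd margin
  allows; offsets beyond `floor(margin/2)` raise an "excessive motion"
  error (or drop the frame under the `"drop"` policy).
* `register_series()` searches the template only within
  `floor(margins/2)` pixels of its reference position — the largest motion
  that could still be compensated — which makes matching cost independent
  of frame size and immune to aliases from the periodic spacer mesh.

No rotation, scaling or subpixel refinement is attempted: the estimated
quantity is a single integer shift.

## Per-layer image similarity

Each registered frame is split into its R, G and B layers
(`split_channels()`) and each layer is compared with the corresponding
layer of the reference frame (by default the first, clean frame of the
registered series) using the two-dimensional Pearson coefficient

$$r = \frac{\sum_m \sum_n (A_{mn} - \bar A)(B_{mn} - \bar B)}
  {\sqrt{\big(\sum_m \sum_n (A_{mn}-\bar A)^2\big)
         \big(\sum_m \sum_n (B_{mn}-\bar B)^2\big)}},$$

the ordinary Pearson coefficient of the flattened pixel vectors
(`pearson2d()`, `similarity_series()`). Two properties make it the right
indicator here:

* it is invariant under positive affine intensity changes, so uniform lamp
  drift and global gain changes do not register as dissimilarity;
* a biofilm absorbs blue light most and red least, so the blue-layer
  coefficient falls first and deepest while the red layer stays nearly
  constant — the channel asymmetry *is* the biofouling signature.

Computation is done in double precision on the native 0–255 levels
(Pearson r is scale-invariant, so no prior normalization is needed), and
the result is clamped to `[-1, 1]`. A constant layer (zero variance) yields
a missing value with a recorded reason, never a numeric score: a uniform
frame indicates an instrument fault.

One behaviour worth knowing: the coefficient is *not* monotone in coverage
all the way to full cover. While patches grow, `r_blue` declines; but as
coverage approaches uniformity the attenuation tends toward an affine
intensity change, to which Pearson r is blind, and the coefficient
partially rebounds. The monotone-decline property therefore holds on the
growing, non-saturated regime (the tests use coverage ≤ 0.6), and a
plateau or rebound of `r_blue` late in a run is expected behaviour, not a
defect.

## Process metrics

Two formulas summarize the process records (`carbon_rate()`,
`permeability()`, `derive_series()`):

* carbon rate
  $\dot C = TOC_{Ret}\,\dot V_{Ret} - TOC_{Feed}\,\dot V_{Feed}$ in mg/h
  (mg/L × L/h). Negative values mean organic carbon accumulates inside the
  module (attachment phase); positive values mean biomass is released
  (detachment phase).
* permeability
  $P_w = \dot V_p / (A \cdot TMP_{net})$ in L/(m² h bar).

Net transmembrane pressure is consumed as a measured input; no
osmotic-pressure or temperature correction is applied, and the membrane
area must be supplied by the user (it is rig-specific). Missing inputs
propagate to missing outputs — never silent zeros.

## Onset, plateau and cleaning recovery

`detect_onset()` automates what an operator does by eye: it forms a
baseline band `mean ± k·sd` from the first `baseline_window` samples and
reports the first time the signal leaves the band in the expected
direction for at least `persistence` consecutive samples. Defaults are
`k = 3`, `persistence = 5` and a 24-sample baseline; all three are exposed.
The persistence requirement suppresses isolated excursions such as a noise
spike or a single misregistered frame. Indicator baselines are meaningful
only after fiber conditioning and membrane compaction, so series are
analysed from `start_h = 96` h by default; an optional 24 h rolling-median
detrend (off by default) removes the daily temperature cycle where it
dominates.

`detect_plateau()` reports the earliest time from which the rolling
least-squares slope over a window stays within a tolerance — the
"signal has saturated" call (e.g. a fully overgrown fiber).

`evaluate_cip()` scores each cleaning-in-place event by the fraction of
the accumulated signal loss regained,
`(post - pre) / (baseline - pre)` with flanking-window medians, clamped to
`[0, 1]`. Declining recovery across successive cleanings is the signature
of a maturing, EPS-stabilized biofilm.

## The synthetic scenario generator

`scenario_config()` fixes every parameter of a simulated accelerated
biofouling run; one root seed drives all randomness, so identical
configurations reproduce byte-identical outputs. The generator emulates:

* **Scene**: a bright membrane sheet (8-bit level ~205) with low-frequency
  mottle (sd 12) and the periodic diamond mesh of a feed spacer (period
  ~42 px at full resolution, filaments ~55 levels darker). The mottle makes
  every window feature-rich so template matching has a unique optimum; the
  spacer provides the strong repeating structure a real photograph shows.
* **Camera jitter**: an integer translation per frame, uniform in
  `[-20, 20]` px per axis at full resolution, implemented by cropping a
  larger scene canvas — the planted shift is exact ground truth.
* **Biofilm**: circular patches nucleate at Poisson times (0.6 patches/h
  after onset at 120 h) at uniform positions, radii grow linearly
  (2 px/h at full resolution), and per-pixel coverage is
  `1 - exp(-occupancy)` so overlapping patches saturate. Coverage darkens
  the three layers by factors `(0.15, 0.35, 0.60)` per unit coverage for
  R, G, B — the white-to-brown shift with the blue layer attenuated most.
  Each CIP event removes fraction `efficacy` of the biomass present.
* **Illumination and noise**: multiplicative lamp drift (2% per 100 h) and
  i.i.d. Gaussian pixel noise (sd 2 levels).
* **POF transmission**: conditioning decay
  `(1 - a) + a·exp(-t/τ)` with amplitude `a = 0.2` and `τ = 24` h (the
  decay has essentially converged by 96 h), multiplied by a 1% 24-hour
  modulation (daily temperature cycle) and, for the sensor fiber only, by
  `exp(-k·coverage)` with `k = 2.5`, coverage capped at a plateau of 0.9
  (fully overgrown sensing zone). The reference fiber omits the fouling
  factor; both traces are normalized to 1 at time zero. The coverage here
  is the expected-area summary of the *same* patch set that darkens the
  images, so image and fiber indicators share one latent biofilm.
* **Process records**: feed flow 11.5 L/h, retentate 10.5 L/h, feed TOC
  1 mg/L, membrane area 0.01 m², net TMP 10 bar, baseline permeability
  10 L/(m² h bar). The carbon balance is zero before onset, a negative
  half-sine during attachment (trough 1.5 mg/h), and flips positive once
  at the detachment boundary (160 h). Permeability rises ~3% after the
  feed change (pH-driven surface-charge effect) and declines from 220 h;
  the FCP is flat (100 ± 0.5 mbar) and rises at 0.8 mbar/h from 240 h —
  the last indicator to respond. Fouling-driven features are suppressed
  entirely when the scenario nucleates no biofilm, so null scenarios are
  flat.

The phase spacing (onset 120 h, detachment 160 h, permeability decline
220 h, FCP rise 240 h) mirrors the temporal ordering observed in
accelerated pilot-plant experiments: fiber and image indicators respond
first, permeability later, FCP last. Where the literature reports no
magnitude (diurnal amplitude, jitter size, biofilm colour coordinates),
defaults were chosen once at plausible values and are configurable.

`scaled_scenario()` rescales all pixel-dimensioned parameters (frame size,
jitter, patch growth) together, giving the same study at lower resolution.

### What the generator does not emulate

Real membrane textures and lighting inhomogeneity; rotation, scale or
subpixel camera motion; demosaicing and other camera artifacts; microbial
community composition or any mechanistic growth kinetics beyond the
patch model; scaling (inorganic crystallization); osmotic-pressure
dynamics. Passing the bundled studies therefore demonstrates that the
*algorithms* behave as specified under controlled statistics — not that
the thresholds are tuned for any particular plant.

## Validation studies and problem sizes

The package validates itself on four study designs (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`):

* *Dimensional worked example*: ten full-resolution 2064 x 3088 x 3 frames
  registered with default margins to 1937 x 2913 x 3.
* *Oracle equivalence*: the FFT NCC against a brute-force per-window
  Pearson loop on 1000 random instances up to 32 x 32, and `pearson2d()`
  against a scalar-loop evaluation on random matrices.
* *Replicate studies* at quarter resolution (516 x 772, 3 h imaging
  cadence, fiber and process records hourly, 360 h duration): detection
  ordering (POF/blue before permeability decline before FCP rise) and
  final channel ordering over 20 replicates; CIP recovery ranking with
  efficacies 0.9 then 0.5 over 20 replicates; planted-shift recovery over
  50-frame series.
* *Null studies* (no fouling, 1/16 resolution): the false-positive rate of
  the full detector battery over 100 replicates at default settings.

These sizes are the package's chosen compromise between statistical power
and a test suite that runs in minutes on a laptop.

## Known limitations

* The translation-only motion model cannot absorb rotation; a rotated
  frame lowers the NCC peak and, past the margin room, is rejected rather
  than corrected.
* Pearson similarity saturates (and can rebound) at near-uniform coverage;
  onset detection is unaffected, but the coefficient is not a coverage
  estimator.
* The onset detector assumes an approximately stationary baseline after
  the conditioning cutoff; strong monotone drifts inside the baseline
  window widen the band and delay detection.
* CIP recovery compares flanking medians; cleanings spaced closer than the
  flanking window, or events during steep transients, blur the estimate.
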