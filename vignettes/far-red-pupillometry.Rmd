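---
title: "Far-red pupillometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Far-red pupillometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(farredplr)
```

## Why far red

Iris melanin absorbs visible light so strongly that in RGB video a
dark-brown iris and the pupil aperture are both nearly black, and pupil
segmentation collapses exactly for the populations most often studied.
Melanin absorption falls steeply with wavelength across the visible range,
so restricting imaging to the far-red band (630–700 nm) — still inside the
passband of commodity RGB camera filters — leaves the iris bright and the
pupil dark regardless of pigmentation. `farredplr` implements the analysis
side of this measurement principle: a ground-truth simulator of the
phenomenon, pupil segmentation, the pupil–iris contrast statistic, PLR
trace processing and device-agreement statistics.

## The spectral model

The simulator collapses wavelength-resolved absorption to one effective
melanin absorption coefficient per imaging condition, applied
Beer–Lambert style:

\[ R_\text{iris}(m, b) \;=\; R_0 \, e^{-m\,\alpha_b}, \]

with \(R_0\) the unpigmented iris base reflectance (default 0.8), \(m\)
the dimensionless melanin load and \(\alpha_b\) the band coefficient
(`far_red` 0.18, `full_visible` 0.9 per unit load; for RGB renders the
red/green/blue channels use 0.9/1.35/1.8 so the iris is reddest in the red
channel). The coefficients are not fitted to any measured spectrum; they
are chosen so that the qualitative ordering the method rests on — far-red
contrast strictly above full-visible contrast, with the gap growing with
melanin load — holds over the whole plausible pigmentation range, which is
all the downstream claims require. `melanin_presets` (`blue` 0.3,
`light_brown` 1.0, `dark_brown` 3.0) anchor the load scale: at load 3 the
full-visible iris sits ~8 intensity levels above the pupil (out of 255)
while the far-red iris sits ~113 above, and at load 0.3 the two conditions
differ by only ~25 %. Frames are rendered concentrically (sclera annulus,
iris annulus, pupil disc) with hard edges, plus saturated glare discs and
additive Gaussian noise, clipped to [0, 255]. In-memory frames are doubles
on the 8-bit scale; quantisation to 8-bit integers happens only on PNG
write, so the renderer's closed forms (e.g. contrast =
\(255(R_\text{iris} - R_\text{pupil})\) in noiseless frames) are exact.

## The kinetic model

The stimulus protocol is fixed by the measurement (1 s dark, 1 s
flashlight, 3 s dark, 60 Hz; 300 frames), but pupil kinetics are not: the
generator uses the simplest law matching observed PLR shapes — baseline
\(D_0\) until one latency \(L\) (default 0.2 s) after stimulus onset,
mono-exponential constriction toward \(D_0(1-A)\) with time constant
\(\tau_c\) (default 0.15 s), then from stimulus offset (+ latency)
mono-exponential redilation with \(\tau_r\) (default 0.7 s) toward the
partial-recovery asymptote \(D_\min + \rho\,(D_0 - D_\min)\), \(\rho\) the
redilation fraction (default 0.6). With the default \(\tau_c\), the
constriction phase comes within 0.2 % of the floor \(D_0(1-A)\), so the
floor doubles as the trace minimum. This law is a stand-in for testing the
pipeline; the package makes no quantitative claims about constriction
speed or latency biomarkers.

## Pupil detection

The published pipeline uses a CNN whose weights are not available; the
far-red design, however, makes the pupil the darkest compact region *by
construction*, which a classical detector exploits directly:

1. red-channel extraction (optional integer downscale, default off);
2. global threshold at the deepest valley of the Gaussian-smoothed
   intensity histogram (bandwidth 3 levels) between the two darkest modes,
   modes closer than 10 levels merged, modes below 0.05 % of the pixel
   count ignored;
3. morphological closing of the binary dark mask with a disc of radius
   4 px, in-painting saturated glare specks inside the pupil;
4. largest dark connected component; moment-based ellipse fit (for a
   filled ellipse the variance along a principal axis is
   (semi-axis)²/4);
5. diameter = diameter of the circle with the same area as the fitted
   ellipse (rotation-stable, unlike a mean-axis convention);
   confidence = circularity \(4\pi A / P^2\) clipped to [0, 1].

Failure is a state, not an exception: frames with intensity range below
12 levels, fewer than two histogram modes, or whose best component fails
the area (50 px² to 40 % of the frame), circularity (≥ 0.35) or
surround-contrast (≥ 10 levels) checks return `valid = FALSE`; video
processing flags those samples as blinks. On full-visible frames of dark
irises the pupil/iris boundary genuinely disappears and the detector may
return the whole iris disc or nothing — the method's claim is about the
contrast ordering, not about any specific failure mode there.

A consequence worth stating: with far-red contrast around 100 intensity
levels and pixel noise of a few levels, no mask pixel ever crosses the
threshold, so detection is *exactly* reproducible across noise seeds and
the residual diameter error is pure rasterisation (≈ ±0.5 px). This is the
designed-for regime, not an artefact.

## Block selection and the contrast statistic

Both blocks are 15 × 15 (225 pixels). The pupil block is centred on the
detected centre; the iris block at twice the pupil radius from the centre
along a 45° diagonal. Glare avoidance is automated: among the four
diagonal candidates (45°, 135°, 225°, 315°, measured from
image-horizontal, upper-right first), the in-frame candidate with the
smallest within-block variance is chosen — a glare disc inside a block
inflates its variance by orders of magnitude — and if every candidate
contains saturated pixels (≥ 250) the candidates are shifted radially by
±0.25 pupil radius and re-evaluated. The block statistic is the mean
(`statistic = "median"` is available); the median is used only for CIELAB
iris luminance, where the block-median convention is part of the
definition. The angle convention is immaterial under variance-minimising
selection but is pinned for reproducibility.

sRGB → CIELAB conversion is implemented from the standard formulas (D65,
2° observer, official transfer function), with the white point taken as
the image of (1, 1, 1) under the sRGB matrix itself so that pure white
maps to L* = 100 and pure black to L* = 0 exactly. Published reference
implementations differ in the fourth decimal of the sRGB matrix; the test
suite compares against `grDevices::convertColor` at 1 % tolerance and
against the endpoints exactly. Eye-colour labels are inputs (self-assessed
in the source study); they are never inferred from L*.

## Trace processing

* **Downsampling** 60 → 30 Hz uses the mean over each pair of samples
  (noise-suppressing; strict decimation available via
  `method = "decimate"`); a window containing any blink-flagged sample is
  blink-flagged; a trailing partial window is dropped.
* **Percent change from mean** uses the mean over non-excluded samples as
  the reference \( \bar d \): blink samples are spurious diameters and
  would bias it. Percent change and mean-downsampling are both affine in
  the diameter, so the two operations commute on blink-free traces; the
  pipeline nevertheless pins the order downsample-first.
* **Blink flagging** for camera traces: a sample is flagged when detection
  is invalid or when its diameter deviates from the median of its 5
  nearest neighbours by more than 20 % of that local median (dropout
  spikes). Reference-device traces carry their own hardware blink flags.
* **Alignment** automates the manual alignment of button-press-started
  recordings: integer-sample lags in ±0.5 s (default) are scanned and the
  lag maximising Pearson correlation over the jointly non-excluded overlap
  is applied, ties broken toward zero lag; fewer than 10 jointly usable
  samples at every lag is an error.
* **Joint exclusion**: a sample flagged in either trace is excluded from
  both, so both devices' statistics are computed on identical time points.

Agreement is MAE in percentage points, Pearson r, and Bland–Altman bias
with limits bias ± 1.96 · SD of the pairwise differences (sample SD, n−1);
cohort summaries are the arithmetic mean/SD of per-subject values.

## What the generator does and does not emulate

It reproduces the features the pipeline's correctness depends on: the
spectral contrast ordering and its growth with melanin load, PLR-shaped
dynamics under the 5 s protocol, eyelid occlusions with known timing,
saturated corneal glare near the pupil boundary, sensor noise, and exact
ground truth for every frame. It does **not** emulate iris texture,
eyelashes, off-axis gaze or eye movement, motion blur, smartphone
computational photography (local tone mapping would alter contrast),
flashlight spectrum or the neutral-density filter, or consensual-response
asymmetries between eyes. Passing the synthetic cohort therefore
demonstrates that the *analysis chain* is correct and self-consistent at
realistic signal levels — not that any specific phone achieves the
published real-participant agreement, which would require the undeposited
study recordings.

For the same reason the synthetic cohort's agreement (MAE ≈ 0.15 pp,
r ≈ 1.0) is *better* than the published real-data values (MAE ≈ 2.25 %,
r = 0.93): the synthetic comparison pits the pipeline against its own
ground truth, with no second physical device, no gaze drift and no
millimetre-to-pixel mismatch. The acceptance thresholds (cohort mean MAE
≤ 2.5 pp, mean r ≥ 0.95) are deliberately placed at the real-data scale
as an upper bound on acceptable pipeline error.

## Problem sizes and runtime choices

The shipped checks use frames of 240 × 320 px (pupils of 30–90 px
diameter, iris radius 90 px, centre (120, 160)), 5 s × 60 Hz = 300-frame
videos, an 11-subject synthetic cohort spanning baseline diameter
40–80 px, constriction amplitude 0.15–0.4, melanin load 0.3–3.0 and noise
SD 2–5 with one blink per recording, and a 100-frame segmentation sweep.
These sizes exercise every code path at the study's own protocol scale
while keeping a full test-plus-acceptance run within a few minutes on one
CPU; nothing in the implementation depends on them.

## Known limitations

* No absolute (millimetre) pupil size from camera traces — pixel scale
  depends on unmeasured camera-to-eye distance; only relative change is
  meaningful, which is why all agreement statistics operate on
  percent-change traces.
* No eye-movement correction; the simulator keeps the pupil centre fixed.
* The classical detector assumes a single pupil in frame and presumes the
  far-red contrast regime; it is the pluggable default backend, not a
  reimplementation of the published CNN, and equivalence is asserted only
  at the level of validation statistics on synthetic data.
* The published per-cell cross-device contrast values depend on
  unavailable study images; only the printed per-participant means are
  used, as shipped in `inst/extdata/table1_cross_device.csv`.
```{r session}
sessionInfo()
```
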