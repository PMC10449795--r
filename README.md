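# farredplr

Analysis pipeline for **far-red smartphone pupillometry** — measuring the
pupillary light reflex (PLR) with an ordinary RGB camera by imaging the eye
at the far-red edge of the visible spectrum (630–700 nm).

## The problem

Pupillometry normally requires a near-infrared pupilometer: in the visible
spectrum, iris melanin absorbs so strongly that a dark-brown iris is nearly
indistinguishable from the black pupil aperture. Melanin absorption falls
off steeply toward the red end of the spectrum, so when the eye is imaged
only in the far-red band the iris reflects brightly while the pupil stays
dark — restoring the pupil–iris contrast that segmentation needs, even for
heavily pigmented eyes.

The central statistic is the **pupil–iris contrast**

```
PupilIrisContrast = IrisPixelIntensity − PupilPixelIntensity
```

with each intensity a block statistic over a 15 × 15 patch of representative
pixels (pupil patch at the pupil centre; iris patch at twice the pupil
radius along a 45° diagonal, routed around corneal glare), and the
**contrast percent increase** between spectral conditions

```
Contrast%Increase = 100 · (Contrast_far_red − Contrast_full) / |Contrast_full|
```

PLR traces from two devices are compared after downsampling to a common
30 Hz rate, joint blink exclusion, and normalisation to percent change from
mean, `100 · (d − d̄)/d̄`; agreement is summarised by mean absolute error
(MAE, percentage points), Pearson r, and Bland–Altman bias with 1.96·SD
limits of agreement.

Because no study data are deposited, the package ships a synthetic
eye-video generator with known ground truth: concentric sclera/iris/pupil
rendering with Beer–Lambert melanin attenuation per spectral band, a
latency + mono-exponential PLR kinetic model under the 1 s dark / 1 s
flash / 3 s dark protocol at 60 Hz, blinks and corneal glare. Every
downstream stage is tested against this generator.

## Worked example

```r
library(farredplr)

## a dark-brown synthetic eye, imaged in both spectral conditions
eye   <- eye_params(melanin_load = melanin_presets[["dark_brown"]], noise_sd = 3)
frame <- render_eye_frame(eye, pupil_diameter_px = 60,
                          band = spectral_band("far_red"), seed = 42)
det   <- detect_pupil(frame)
det
#> Pupil detection: center (120.0, 160.0), diameter 59.9 px, confidence 1.00

blocks <- select_pixel_blocks(frame, det)
far_c  <- pupil_iris_contrast(frame, blocks$pupil, blocks$iris, condition = "far_red")
far_c
#> Pupil-iris contrast: 113.3 (iris 118.7 - pupil 5.4)  [far_red]

full   <- extract_red_channel(render_eye_frame(eye, 60, spectral_band("full_visible"), seed = 42))
full_c <- pupil_iris_contrast(full, blocks$pupil, blocks$iris, condition = "full_visible")
full_c
#> Pupil-iris contrast: 8.2 (iris 13.6 - pupil 5.4)  [full_visible]

contrast_percent_increase(far_c$contrast, full_c$contrast)
#> [1] 1285.9
```

Under full-visible light this dark iris is barely 8 intensity levels
brighter than the pupil — essentially unsegmentable — while far-red imaging
raises the contrast to 113 levels, a ~1300 % increase.

An end-to-end validation run (render a 5 s, 60 Hz PLR video with one blink,
segment it, then compare measured vs. true traces after downsampling,
percent-change normalisation, alignment and joint blink exclusion):

```r
run <- simulate_and_validate(params = eye,
                             dyn = pupil_dynamics(baseline_diameter_px = 60,
                                                  constriction_amplitude = 0.3),
                             blink_times_s = 3.2, seed = 42)
run$agreement
#> PLR agreement: MAE 0.12 pp, Pearson r 1.000, bias -0.00 [-0.34, 0.34], n = 145
```

A command-line interface wrapping the same functions is installed at
`inst/cli/farredplr` with subcommands `simulate`, `plr`, `contrast`,
`validate` and `crossdevice` (see `?cli_main`).

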