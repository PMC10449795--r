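test_that("iris reflectance follows Beer-Lambert attenuation of the base value", {
  p <- quiet_eye(melanin_load = 0)
  expect_equal(iris_reflectance(p, far_red()), p$iris_base_reflectance)
  expect_equal(iris_reflectance(p, full_visible()), p$iris_base_reflectance)

  # closed form, evaluated independently of the implementation's band object
  p2 <- eye_params(melanin_load = 2, iris_base_reflectance = 0.8,
                   glare_spots = NULL)
  band <- spectral_band("far_red")
  band$effective_melanin_absorption <- 0.5
  expect_equal(iris_reflectance(p2, band), 0.8 * exp(-1), tolerance = 1e-12)

  # strictly decreasing in melanin load, for both bands
  loads <- seq(0, 4, by = 0.25)
  for (b in list(far_red(), full_visible())) {
    vals <- vapply(loads, function(m) iris_reflectance(quiet_eye(m), b), 1)
    expect_true(all(diff(vals) < 0))
  }

  # far-red always exceeds full-visible at positive load
  for (m in c(0.1, 1, 3)) {
    p3 <- quiet_eye(m)
    expect_gt(iris_reflectance(p3, far_red()),
              iris_reflectance(p3, full_visible()))
  }
})

test_that("spectral band encodes weaker melanin absorption in the far red", {
  expect_lt(spectral_band("far_red")$effective_melanin_absorption,
            spectral_band("full_visible")$effective_melanin_absorption)
  ch <- spectral_band("full_visible")$channel_absorption
  expect_true(ch[["red"]] <= ch[["green"]] && ch[["green"]] <= ch[["blue"]])
})

test_that("simulated PLR diameter trace follows the kinetic model", {
  proto <- plr_protocol()
  # zero amplitude: constant baseline
  tr0 <- simulate_plr_diameter(pupil_dynamics(constriction_amplitude = 0), proto)
  expect_equal(tr0$diameter, rep(60, 300))

  dyn <- pupil_dynamics(baseline_diameter_px = 60, constriction_amplitude = 0.3,
                        latency_s = 0.2)
  tr <- simulate_plr_diameter(dyn, proto)
  expect_equal(nrow(tr), 300)
  expect_equal(diff(tr$time_s), rep(1 / 60, 299))
  # latency: baseline until stimulus onset + latency
  expect_true(all(tr$diameter[tr$time_s < 1.2] == 60))
  # minimum reaches D0 * (1 - A) to within the model's residual (< 1%)
  expect_equal(min(tr$diameter), 42, tolerance = 0.01)
  expect_true(all(tr$diameter > 0 & tr$diameter <= 60))
  # redilation recovers roughly the configured fraction by the end
  recovered <- (tr$diameter[300] - min(tr$diameter)) / (60 - min(tr$diameter))
  expect_equal(recovered, dyn$redilation_fraction, tolerance = 0.05)
})

test_that("frame count follows duration times frame rate for any configuration", {
  for (fps in c(24, 30, 60)) {
    proto <- plr_protocol(frame_rate_hz = fps)
    tr <- simulate_plr_diameter(pupil_dynamics(), proto)
    expect_equal(nrow(tr), round(5 * fps))
  }
  proto2 <- plr_protocol(pre_stimulus_s = 0.5, stimulus_s = 0.5,
                         post_stimulus_s = 2, frame_rate_hz = 60)
  expect_equal(nrow(simulate_plr_diameter(pupil_dynamics(), proto2)), 180)
})

test_that("rendering is deterministic and honours the geometry contract", {
  p <- eye_params(noise_sd = 4)
  f1 <- render_eye_frame(p, 60, far_red(), seed = 11)
  f2 <- render_eye_frame(p, 60, far_red(), seed = 11)
  expect_identical(f1, f2)
  f3 <- render_eye_frame(p, 60, far_red(), seed = 12)
  expect_false(identical(f1, f3))
  expect_error(render_eye_frame(p, 2 * p$iris_radius_px + 5, far_red()),
               "iris radius")

  # noiseless, glare-free pupil block is exactly constant
  p0 <- quiet_eye(melanin_load = 2)
  f <- render_eye_frame(p0, 60, far_red(), seed = 1)
  blk <- f[113:127, 153:167]
  expect_true(all(blk == 255 * p0$pupil_reflectance))
  expect_true(all(f >= 0 & f <= 255))

  # full-visible render is 3-channel with iris reddest in the red channel
  fv <- render_eye_frame(p0, 60, full_visible(), seed = 1)
  expect_equal(dim(fv)[3], 3L)
  iris_px <- cbind(60, 160)
  expect_gte(fv[60, 160, 1], fv[60, 160, 2])
  expect_gte(fv[60, 160, 2], fv[60, 160, 3])
})

test_that("dark irises show larger pupil-iris contrast under far red than full visible", {
  pair <- render_condition_pair(melanin_load = 3)
  pupil_mean <- function(f) mean(f[113:127, 153:167])
  iris_mean <- function(f) mean(f[56:70, 153:167])
  c_far <- iris_mean(pair$far) - pupil_mean(pair$far)
  c_full <- iris_mean(pair$full) - pupil_mean(pair$full)
  expect_gt(c_far, c_full)
  expect_gt(c_far, 0)
})

test_that("rendered PLR video pairs one frame per truth sample and flags blinks", {
  p <- quiet_eye(noise_sd = 2)
  vid <- render_plr_video(p, pupil_dynamics(), plr_protocol(), far_red(),
                          seed = 4)
  expect_length(vid$frames, 300)
  expect_false(any(vid$truth$blink))

  vid_b <- render_plr_video(p, pupil_dynamics(), plr_protocol(), far_red(),
                            blink_times_s = 2.0, seed = 4)
  in_window <- vid_b$truth$time_s >= 2.0 & vid_b$truth$time_s < 2.15
  expect_identical(vid_b$truth$blink, in_window)

  expect_error(render_plr_video(p, pupil_dynamics(), plr_protocol(), far_red(),
                                blink_times_s = c(2.0, 2.05)),
               "overlap")
  expect_error(render_plr_video(p, pupil_dynamics(), plr_protocol(), far_red(),
                                blink_times_s = 7),
               "within")
})
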