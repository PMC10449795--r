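test_that("block selection follows the 2x-radius diagonal geometry and avoids glare", {
  pair <- render_condition_pair(melanin_load = 1)
  det <- detect_pupil(pair$far)
  blocks <- select_pixel_blocks(pair$far, det)
  expect_equal(blocks$pupil$top_left + 7, round(det$center), tolerance = 0.6)
  # iris block centre sits 2 * radius = diameter away from the pupil centre
  iris_ctr <- blocks$iris$top_left + 7
  dist <- sqrt(sum((iris_ctr - det$center)^2))
  expect_equal(dist, det$diameter_px, tolerance = 0.03)

  # a glare spot at the preferred 45-degree candidate forces another diagonal
  glare_at_45 <- data.frame(row = 120 - 60 / sqrt(2), col = 160 + 60 / sqrt(2),
                            radius_px = 3, intensity = 255)
  pg <- eye_params(melanin_load = 1, noise_sd = 0, glare_spots = glare_at_45)
  fg <- render_eye_frame(pg, 60, far_red(), seed = 1)
  bg <- select_pixel_blocks(fg, detect_pupil(fg))
  expect_gt(bg$iris$top_left[2] + 7, 0)
  expect_lt(bg$iris$top_left[2] + 7, 160)  # moved off the right-hand diagonal

  expect_error(select_pixel_blocks(pair$far, structure(
    list(valid = FALSE), class = "pupil_detection")), "valid")
})

test_that("pupil-iris contrast is the block-statistic difference", {
  f <- matrix(0, 100, 100)
  f[11:25, 11:25] <- 50    # "pupil" block
  f[61:75, 61:75] <- 200   # "iris" block
  pb <- pixel_block(c(11, 11), label = "pupil")
  ib <- pixel_block(c(61, 61), label = "iris")
  m <- pupil_iris_contrast(f, pb, ib)
  expect_equal(m$contrast, 150)
  expect_equal(m$contrast, m$iris_intensity - m$pupil_intensity)
  expect_equal(pupil_iris_contrast(f, pb, pb)$contrast, 0)

  # closed form of the noiseless renderer
  p <- quiet_eye(melanin_load = 2)
  fr <- render_eye_frame(p, 60, far_red(), seed = 1)
  det <- detect_pupil(fr)
  blocks <- select_pixel_blocks(fr, det)
  m2 <- pupil_iris_contrast(fr, blocks$pupil, blocks$iris)
  expect_equal(m2$contrast,
               255 * (iris_reflectance(p, far_red()) - p$pupil_reflectance),
               tolerance = 1e-12)

  expect_error(pupil_iris_contrast(array(0, c(10, 10, 3)), pb, ib),
               "single-channel")
})

test_that("contrast is affine-equivariant in pixel intensity", {
  pair <- render_condition_pair(melanin_load = 1.5)
  det <- detect_pupil(pair$far)
  blocks <- select_pixel_blocks(pair$far, det)
  base <- pupil_iris_contrast(pair$far, blocks$pupil, blocks$iris)$contrast
  shifted <- pupil_iris_contrast(pair$far + 17, blocks$pupil, blocks$iris)$contrast
  scaled <- pupil_iris_contrast(pair$far * 0.5, blocks$pupil, blocks$iris)$contrast
  expect_equal(shifted, base, tolerance = 1e-12)
  expect_equal(scaled, 0.5 * base, tolerance = 1e-12)
})

test_that("percent increase matches the direct formula and its sign conventions", {
  expect_equal(contrast_percent_increase(10, 2), 400)
  expect_equal(contrast_percent_increase(5, -5), 200)
  expect_equal(contrast_percent_increase(7, 7), 0)
  expect_error(contrast_percent_increase(5, 0), "zero")

  set.seed(99)
  far <- stats::runif(1000, -50, 250)
  full <- stats::runif(1000, -50, 250)
  full[full == 0] <- 1
  expect_equal(contrast_percent_increase(far, full),
               100 * (far - full) / abs(full), tolerance = 1e-12)
})

test_that("percent increase on simulator pairs is positive and grows with melanin", {
  pcts <- vapply(c(0.5, 1, 1.5, 2, 2.5, 3), function(m) {
    pair <- render_condition_pair(m)
    det <- detect_pupil(pair$far)
    blocks <- select_pixel_blocks(pair$far, det)
    c_far <- pupil_iris_contrast(pair$far, blocks$pupil, blocks$iris)$contrast
    c_full <- pupil_iris_contrast(pair$full, blocks$pupil, blocks$iris)$contrast
    contrast_percent_increase(c_far, c_full)
  }, 1)
  expect_true(all(pcts > 0))
  expect_true(all(diff(pcts) > 0))
})

test_that("sRGB to CIELAB matches the reference converter and is monotone in gray", {
  expect_identical(as.numeric(srgb_to_lab(c(255, 255, 255))[, "L"]), 100)
  expect_identical(as.numeric(srgb_to_lab(c(0, 0, 0))[, "L"]), 0)

  grays <- seq(0, 255, by = 15)
  mine <- srgb_to_lab(cbind(grays, grays, grays))
  ref <- grDevices::convertColor(cbind(grays, grays, grays) / 255,
                                 from = "sRGB", to = "Lab")
  expect_equal(unname(mine[, "L"]), unname(ref[, 1]), tolerance = 1e-4)
  expect_true(all(diff(mine[, "L"]) > 0))
  expect_equal(unname(mine[, c("a", "b")]), unname(ref[, 2:3]), tolerance = 1e-4)

  # a saturated colour, against the same independent reference; reference
  # implementations differ slightly in sRGB-matrix precision, hence 1%
  col <- c(180, 60, 30)
  expect_equal(unname(srgb_to_lab(col)[1, ]),
               unname(grDevices::convertColor(matrix(col / 255, 1),
                                              from = "sRGB", to = "Lab")[1, ]),
               tolerance = 0.01)
})

test_that("iris luminance is the median L* over the block", {
  fv <- render_eye_frame(quiet_eye(melanin_load = 1), 60, full_visible(),
                         seed = 2)
  blk <- pixel_block(c(56, 153), label = "iris")
  rec <- iris_luminance(fv, blk, "light_brown")
  px <- cbind(as.vector(fv[56:70, 153:167, 1]),
              as.vector(fv[56:70, 153:167, 2]),
              as.vector(fv[56:70, 153:167, 3]))
  expect_equal(rec$iris_luminance, stats::median(srgb_to_lab(px)[, "L"]))
  expect_true(rec$iris_luminance >= 0 && rec$iris_luminance <= 100)
  expect_error(iris_luminance(matrix(0, 10, 10), blk), "3-channel")

  # darker irises (higher melanin) give lower L*
  lum <- vapply(melanin_presets, function(m) {
    f <- render_eye_frame(quiet_eye(m), 60, full_visible(), seed = 2)
    iris_luminance(f, blk)$iris_luminance
  }, 1)
  expect_true(all(diff(lum) < 0))
})

test_that("cross-device table aggregates per participant and by eye colour", {
  long <- data.frame(participant = rep(1:3, each = 2),
                     device = rep(c("a", "b"), 3),
                     percent_increase = c(100, 200, 300, 300, 10, 30),
                     eye_color = rep(c("blue", "dark_brown", "dark_brown"),
                                     each = 2))
  tab <- cross_device_table(long)
  expect_equal(tab$per_participant$mean, c(150, 300, 20))
  expect_equal(tab$per_participant$sd,
               c(stats::sd(c(100, 200)), 0, stats::sd(c(10, 30))))
  expect_equal(tab$grand_mean, mean(c(150, 300, 20)))
  expect_equal(unname(tab$grand_mean_by_color[["dark_brown"]]), 160)

  # constant entries: mean c, sd 0
  const <- data.frame(participant = rep(1, 3), device = c("a", "b", "c"),
                      percent_increase = rep(42, 3))
  tc <- cross_device_table(const)
  expect_equal(tc$per_participant$mean, 42)
  expect_equal(tc$per_participant$sd, 0)

  # single-device rows have undefined sd; empty input errors
  single <- data.frame(participant = 1, device = "a", percent_increase = 5)
  expect_true(is.na(cross_device_table(single)$per_participant$sd))
  expect_error(cross_device_table(single[0, ]), "empty")
})
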