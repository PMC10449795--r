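#' Geometry and reflectance of a synthetic eye
#'
#' Bundles the parameters the renderer needs to draw a concentric
#' sclera / iris / pupil eye image. Iris pigmentation is controlled by a
#' dimensionless melanin load: the rendered iris reflectance is the base
#' reflectance attenuated Beer-Lambert style by the melanin absorption of
#' the imaging band (see [iris_reflectance()]). Dark-brown irises
#' correspond to high melanin loads, blue irises to low loads.
#'
#' @param image_height_px,image_width_px Frame size in pixels.
#' @param pupil_center `(row, col)` of the pupil centre, in pixels
#'   (row 1 at the top).
#' @param iris_radius_px Outer iris radius in pixels; must exceed any
#'   pupil radius rendered with these parameters.
#' @param sclera_reflectance,iris_base_reflectance,pupil_reflectance
#'   Reflectances in `[0, 1]`. The pupil aperture is nearly black
#'   (default 0.02); the iris base reflectance is the unpigmented value
#'   before melanin attenuation.
#' @param melanin_load Nonnegative iris pigment density (0 = no melanin).
#'   See [melanin_presets] for eye-colour-equivalent settings.
#' @param glare_spots Specular reflections, as a data frame with columns
#'   `row`, `col`, `radius_px`, `intensity` (0-255); `NULL` for none.
#'   The default places two small saturated spots near the boundary of a
#'   60 px pupil, mimicking LED reflections off the cornea.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise,
#'   in 8-bit intensity units.
#'
#' @return An object of class `"eye_params"`.
#' @seealso [render_eye_frame()], [iris_reflectance()]
#' @export
eye_params <- function(image_height_px = 240L, image_width_px = 320L,
                       pupil_center = c(120, 160), iris_radius_px = 90,
                       sclera_reflectance = 0.85, iris_base_reflectance = 0.8,
                       melanin_load = 1, pupil_reflectance = 0.02,
                       glare_spots = default_glare_spots(pupil_center),
                       noise_sd = 3) {
  assert_scalar_in(image_height_px, "image_height_px", 16)
  assert_scalar_in(image_width_px, "image_width_px", 16)
  if (length(pupil_center) != 2L || !all(is.finite(pupil_center)))
    stopf("`pupil_center` must be (row, col)")
  assert_scalar_in(iris_radius_px, "iris_radius_px", 1)
  assert_scalar_in(sclera_reflectance, "sclera_reflectance", 0, 1)
  assert_scalar_in(iris_base_reflectance, "iris_base_reflectance", 0, 1)
  assert_scalar_in(pupil_reflectance, "pupil_reflectance", 0, 1)
  assert_scalar_in(melanin_load, "melanin_load", 0)
  assert_scalar_in(noise_sd, "noise_sd", 0)
  if (!is.null(glare_spots)) {
    glare_spots <- as.data.frame(glare_spots)
    need <- c("row", "col", "radius_px", "intensity")
    if (!all(need %in% names(glare_spots)))
      stopf("`glare_spots` needs columns %s", paste(need, collapse = ", "))
  }
  structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pupil_center = as.numeric(pupil_center),
    iris_radius_px = iris_radius_px,
    sclera_reflectance = sclera_reflectance,
    iris_base_reflectance = iris_base_reflectance,
    melanin_load = melanin_load,
    pupil_reflectance = pupil_reflectance,
    glare_spots = glare_spots,
    noise_sd = noise_sd,
    bit_depth = 8L
  ), class = "eye_params")
}

#' @export
print.eye_params <- function(x, ...) {
  cat("Synthetic eye:", x$image_height_px, "x", x$image_width_px, "px,",
      "iris radius", x$iris_radius_px, "px, melanin load", x$melanin_load, "\n")
  cat("  reflectance (sclera/iris base/pupil):",
      x$sclera_reflectance, "/", x$iris_base_reflectance, "/",
      x$pupil_reflectance, "  noise sd:", x$noise_sd, "\n")
  invisible(x)
}

#' Default corneal glare spots
#'
#' Two small saturated discs near the boundary of a 60 px diameter pupil,
#' offset from the pupil centre; block selection must route around them.
#'
#' @param pupil_center `(row, col)` pupil centre in pixels.
#' @return Data frame with columns `row`, `col`, `radius_px`, `intensity`.
#' @export
default_glare_spots <- function(pupil_center = c(120, 160)) {
  data.frame(
    row = pupil_center[1] + c(-18, -20),
    col = pupil_center[2] + c(-18, 22),
    radius_px = c(3, 2.5),
    intensity = c(255, 255)
  )
}

#' Melanin loads emulating common iris colours
#'
#' Dimensionless melanin loads used throughout the examples and tests to
#' stand in for self-assessed eye colours: light/blue irises carry little
#' melanin, dark-brown irises a lot.
#'
#' @format Named numeric vector (`blue`, `light_brown`, `dark_brown`).
#' @export
melanin_presets <- c(blue = 0.3, light_brown = 1.0, dark_brown = 3.0)

#' Spectral imaging band
#'
#' The simulator collapses wavelength-resolved melanin absorption to one
#' effective absorption coefficient per imaging condition. Melanin absorbs
#' far less at the far-red edge of the visible range (630-700 nm) than over
#' the full visible spectrum, so the far-red coefficient is the smaller of
#' the two; that ordering is what makes the iris image brightly against the
#' dark pupil under far-red illumination even for heavily pigmented eyes.
#'
#' For `full_visible` the per-channel coefficients make the iris reddest in
#' the red channel (red absorption <= green <= blue), so extracting the red
#' channel is meaningful in both conditions.
#'
#' @param name `"far_red"` or `"full_visible"`.
#' @return An object of class `"spectral_band"` with fields `name`,
#'   `effective_melanin_absorption` and (for rendering) per-channel
#'   absorption coefficients.
#' @export
spectral_band <- function(name = c("far_red", "full_visible")) {
  name <- match.arg(name)
  if (name == "far_red") {
    abs_eff <- 0.18
    chan <- c(red = 0.18)
  } else {
    abs_eff <- 0.9
    chan <- c(red = 0.9, green = 1.35, blue = 1.8)
  }
  structure(list(name = name,
                 effective_melanin_absorption = abs_eff,
                 channel_absorption = chan),
            class = "spectral_band")
}

#' Iris reflectance under a spectral band
#'
#' Beer-Lambert-style attenuation of the unpigmented iris reflectance:
#' `iris_base_reflectance * exp(-melanin_load * absorption)`, with the
#' band's effective melanin absorption coefficient. Strictly decreasing in
#' melanin load; for any positive load the far-red value exceeds the
#' full-visible value.
#'
#' @param params An [eye_params()] object.
#' @param band A [spectral_band()] object.
#' @return Reflectance in `[0, 1]`.
#' @export
iris_reflectance <- function(params, band) {
  stopifnot(inherits(params, "eye_params"), inherits(band, "spectral_band"))
  params$iris_base_reflectance *
    exp(-params$melanin_load * band$effective_melanin_absorption)
}

#' Pupil constriction/redilation dynamics
#'
#' A simple kinetic model for the pupillary light reflex: the diameter
#' holds at baseline until one latency after stimulus onset, constricts
#' mono-exponentially toward `D0 * (1 - A)`, then after stimulus offset
#' redilates mono-exponentially toward a partial-recovery asymptote
#' `Dmin + redilation_fraction * (D0 - Dmin)`.
#'
#' @param baseline_diameter_px Baseline (dark-adapted) diameter `D0`, px.
#' @param constriction_amplitude Fractional constriction `A` in `[0, 1)`;
#'   the minimum diameter approaches `D0 * (1 - A)`.
#' @param latency_s Delay between stimulus onset and constriction onset.
#' @param constriction_time_constant_s,redilation_time_constant_s Time
#'   constants of the two exponential phases, seconds.
#' @param redilation_fraction Fraction of the constriction recovered by
#'   the end of the recording, in `[0, 1]`.
#' @return An object of class `"pupil_dynamics"`.
#' @export
pupil_dynamics <- function(baseline_diameter_px = 60,
                           constriction_amplitude = 0.3,
                           latency_s = 0.2,
                           constriction_time_constant_s = 0.15,
                           redilation_time_constant_s = 0.7,
                           redilation_fraction = 0.6) {
  if (!is_scalar_num(baseline_diameter_px) || baseline_diameter_px <= 0)
    stopf("`baseline_diameter_px` must be positive")
  assert_scalar_in(constriction_amplitude, "constriction_amplitude", 0, 1 - 1e-9)
  assert_scalar_in(latency_s, "latency_s", 0)
  if (!is_scalar_num(constriction_time_constant_s) || constriction_time_constant_s <= 0)
    stopf("`constriction_time_constant_s` must be positive")
  if (!is_scalar_num(redilation_time_constant_s) || redilation_time_constant_s <= 0)
    stopf("`redilation_time_constant_s` must be positive")
  assert_scalar_in(redilation_fraction, "redilation_fraction", 0, 1)
  structure(list(baseline_diameter_px = baseline_diameter_px,
                 constriction_amplitude = constriction_amplitude,
                 latency_s = latency_s,
                 constriction_time_constant_s = constriction_time_constant_s,
                 redilation_time_constant_s = redilation_time_constant_s,
                 redilation_fraction = redilation_fraction),
            class = "pupil_dynamics")
}

#' Light-stimulus protocol for a PLR recording
#'
#' The standard 5 s protocol: 1 s of darkness, 1 s flashlight stimulus,
#' 3 s of darkness, sampled at the recording frame rate.
#'
#' @param pre_stimulus_s,stimulus_s,post_stimulus_s Phase durations, s.
#' @param frame_rate_hz Recording frame rate (default 60).
#' @return An object of class `"plr_protocol"`.
#' @export
plr_protocol <- function(pre_stimulus_s = 1, stimulus_s = 1,
                         post_stimulus_s = 3, frame_rate_hz = 60) {
  assert_scalar_in(pre_stimulus_s, "pre_stimulus_s", 0)
  assert_scalar_in(stimulus_s, "stimulus_s", 0)
  assert_scalar_in(post_stimulus_s, "post_stimulus_s", 0)
  if (!is_scalar_num(frame_rate_hz) || frame_rate_hz <= 0)
    stopf("`frame_rate_hz` must be positive")
  structure(list(pre_stimulus_s = pre_stimulus_s, stimulus_s = stimulus_s,
                 post_stimulus_s = post_stimulus_s,
                 frame_rate_hz = frame_rate_hz),
            class = "plr_protocol")
}

protocol_duration <- function(protocol) {
  protocol$pre_stimulus_s + protocol$stimulus_s + protocol$post_stimulus_s
}

plr_diameter_at <- function(t, dyn, protocol) {
  d0 <- dyn$baseline_diameter_px
  a <- dyn$constriction_amplitude
  dmin <- d0 * (1 - a)
  t_on <- protocol$pre_stimulus_s + dyn$latency_s
  t_re <- protocol$pre_stimulus_s + protocol$stimulus_s + dyn$latency_s
  d <- rep(d0, length(t))
  con <- t >= t_on & t < t_re
  d[con] <- dmin + a * d0 * exp(-(t[con] - t_on) / dyn$constriction_time_constant_s)
  re <- t >= t_re
  if (any(re)) {
    d1 <- dmin + a * d0 * exp(-(t_re - t_on) / dyn$constriction_time_constant_s)
    dinf <- d1 + dyn$redilation_fraction * (d0 - d1)
    d[re] <- dinf - (dinf - d1) * exp(-(t[re] - t_re) / dyn$redilation_time_constant_s)
  }
  d
}

#' Simulate a ground-truth pupil diameter trace
#'
#' Evaluates the kinetic model over the protocol's time grid and returns a
#' ground-truth [pupil_trace] (in pixels, 60 Hz by default) with all blink
#' flags false and a constant pupil centre.
#'
#' @param dyn A [pupil_dynamics()] object.
#' @param protocol A [plr_protocol()] object.
#' @param center `(row, col)` pupil centre recorded per sample.
#' @return A `pupil_trace` with columns `time_s`, `diameter`, `blink`,
#'   `center_row`, `center_col`.
#' @export
simulate_plr_diameter <- function(dyn, protocol = plr_protocol(),
                                  center = c(120, 160)) {
  stopifnot(inherits(dyn, "pupil_dynamics"), inherits(protocol, "plr_protocol"))
  dur <- protocol_duration(protocol)
  n <- round(dur * protocol$frame_rate_hz)
  t <- (seq_len(n) - 1) / protocol$frame_rate_hz
  d <- plr_diameter_at(t, dyn, protocol)
  pupil_trace(time_s = t, diameter = d, blink = rep(FALSE, n),
              unit = "px", sample_rate_hz = protocol$frame_rate_hz,
              center_row = rep(center[1], n), center_col = rep(center[2], n))
}

render_channel <- function(params, pupil_radius_px, reflectance_iris) {
  nr <- params$image_height_px
  nc <- params$image_width_px
  rr <- matrix(seq_len(nr), nr, nc) - params$pupil_center[1]
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - params$pupil_center[2]
  dist <- sqrt(rr^2 + cc^2)
  img <- matrix(255 * params$sclera_reflectance, nr, nc)
  img[dist <= params$iris_radius_px] <- 255 * reflectance_iris
  img[dist <= pupil_radius_px] <- 255 * params$pupil_reflectance
  img
}

apply_glare <- function(img, params) {
  if (is.null(params$glare_spots) || nrow(params$glare_spots) == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(nrow(params$glare_spots))) {
    g <- params$glare_spots[i, ]
    hit <- (rr - g$row)^2 + (cc - g$col)^2 <= g$radius_px^2
    img[hit] <- g$intensity
  }
  img
}

#' Render one synthetic eye frame
#'
#' Concentric rendering: sclera background, iris annulus at
#' `255 * iris_reflectance(params, band)` (per channel for
#' `full_visible`), pupil disc at `255 * pupil_reflectance`, plus glare
#' discs and additive Gaussian noise, clipped to `[0, 255]`. Rendering is
#' a pure function of its arguments: the same seed gives bit-identical
#' frames. Intensities are stored as doubles on the 8-bit scale;
#' quantisation to integers happens only when frames are written to PNG.
#'
#' @param params An [eye_params()] object.
#' @param pupil_diameter_px Pupil diameter to draw, px; must be smaller
#'   than twice the iris radius.
#' @param band A [spectral_band()] object; `far_red` renders a
#'   single-channel matrix, `full_visible` an `H x W x 3` RGB array.
#' @param seed Integer seed for the noise field.
#' @return A numeric matrix (far_red) or `H x W x 3` array (full_visible)
#'   with values in `[0, 255]`.
#' @export
render_eye_frame <- function(params, pupil_diameter_px,
                             band = spectral_band("far_red"), seed = 1L) {
  stopifnot(inherits(params, "eye_params"), inherits(band, "spectral_band"))
  if (!is_scalar_num(pupil_diameter_px) || pupil_diameter_px <= 0)
    stopf("`pupil_diameter_px` must be positive")
  if (pupil_diameter_px / 2 >= params$iris_radius_px)
    stopf("pupil radius (%.1f px) must be smaller than the iris radius (%.1f px)",
          pupil_diameter_px / 2, params$iris_radius_px)
  r_pup <- pupil_diameter_px / 2
  base <- params$iris_base_reflectance
  with_seed(seed, {
    if (band$name == "far_red") {
      refl <- base * exp(-params$melanin_load * band$channel_absorption[["red"]])
      img <- render_channel(params, r_pup, refl)
      img <- apply_glare(img, params)
      if (params$noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, params$noise_sd),
                            nrow(img), ncol(img))
      clip255(img)
    } else {
      out <- array(0, c(params$image_height_px, params$image_width_px, 3L))
      for (ch in 1:3) {
        refl <- base * exp(-params$melanin_load * band$channel_absorption[[ch]])
        img <- render_channel(params, r_pup, refl)
        img <- apply_glare(img, params)
        if (params$noise_sd > 0)
          img <- img + matrix(stats::rnorm(length(img), 0, params$noise_sd),
                              nrow(img), ncol(img))
        out[, , ch] <- clip255(img)
      }
      out
    }
  })
}

render_eyelid_frame <- function(params, band, seed) {
  skin <- 0.55
  with_seed(seed, {
    make_one <- function() {
      img <- matrix(255 * skin, params$image_height_px, params$image_width_px)
      if (params$noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, params$noise_sd),
                            nrow(img), ncol(img))
      clip255(img)
    }
    if (band$name == "far_red") {
      make_one()
    } else {
      out <- array(0, c(params$image_height_px, params$image_width_px, 3L))
      for (ch in 1:3) out[, , ch] <- make_one()
      out
    }
  })
}

#' Render a full synthetic PLR video with ground truth
#'
#' Composes [simulate_plr_diameter()] and [render_eye_frame()]: one frame
#' per ground-truth sample. During each blink window (default width
#' 0.15 s) the eye is occluded by an eyelid and the sample's blink flag is
#' set. Per-frame noise seeds are derived deterministically from `seed`.
#'
#' @param params An [eye_params()] object.
#' @param dyn A [pupil_dynamics()] object.
#' @param protocol A [plr_protocol()] object.
#' @param band A [spectral_band()] object.
#' @param blink_times_s Blink onset times within the recording, seconds.
#' @param blink_width_s Blink window width, seconds (default 0.15).
#' @param seed Integer master seed.
#' @return A list with elements `frames` (list of frames) and `truth`
#'   (ground-truth [pupil_trace] with blink flags).
#' @export
render_plr_video <- function(params, dyn, protocol = plr_protocol(),
                             band = spectral_band("far_red"),
                             blink_times_s = numeric(0),
                             blink_width_s = 0.15, seed = 1L) {
  stopifnot(inherits(params, "eye_params"))
  dur <- protocol_duration(protocol)
  if (length(blink_times_s)) {
    if (any(blink_times_s < 0 | blink_times_s > dur))
      stopf("blink times must lie within [0, %g] s", dur)
    bt <- sort(blink_times_s)
    if (length(bt) > 1 && any(diff(bt) < blink_width_s))
      stopf("blink windows overlap")
  }
  truth <- simulate_plr_diameter(dyn, protocol, center = params$pupil_center)
  n <- nrow(truth)
  blink <- rep(FALSE, n)
  for (b in blink_times_s)
    blink <- blink | (truth$time_s >= b & truth$time_s < b + blink_width_s)
  truth$blink <- blink
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    fseed <- as.integer((seed + 7919 * i) %% .Machine$integer.max)
    frames[[i]] <- if (blink[i]) {
      render_eyelid_frame(params, band, fseed)
    } else {
      render_eye_frame(params, truth$diameter[i], band, fseed)
    }
  }
  list(frames = frames, truth = truth)
}
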