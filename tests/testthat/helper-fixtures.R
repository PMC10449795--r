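# Shared fixture builders; every frame is generated in code at test time.

quiet_eye <- function(melanin_load = 1, noise_sd = 0, glare = NULL, ...) {
  eye_params(melanin_load = melanin_load, noise_sd = noise_sd,
             glare_spots = glare, ...)
}

far_red <- function() spectral_band("far_red")
full_visible <- function() spectral_band("full_visible")

# Red-channel frame pair of the same eye under both spectral conditions.
render_condition_pair <- function(melanin_load, diameter = 60, noise_sd = 0,
                                  seed = 1) {
  p <- quiet_eye(melanin_load, noise_sd)
  list(
    far = render_eye_frame(p, diameter, far_red(), seed = seed),
    full = extract_red_channel(
      render_eye_frame(p, diameter, full_visible(), seed = seed)),
    params = p
  )
}

make_trace <- function(d, rate = 60, blink = rep(FALSE, length(d)),
                       unit = "px") {
  pupil_trace(time_s = (seq_along(d) - 1) / rate, diameter = d, blink = blink,
              unit = unit, sample_rate_hz = rate)
}
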