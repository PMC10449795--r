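#' Simulate a PLR recording and validate the pipeline against truth
#'
#' The desk-scale analogue of a device-validation run: renders a synthetic
#' far-red PLR video with known ground truth, segments it frame by frame,
#' and compares the measured trace against the ground-truth trace with
#' both processed identically — downsample to the reference rate, percent
#' change from mean, cross-correlation alignment, joint blink exclusion —
#' before computing agreement statistics.
#'
#' @param params An [eye_params()] object.
#' @param dyn A [pupil_dynamics()] object.
#' @param protocol A [plr_protocol()] object.
#' @param band A [spectral_band()] object.
#' @param blink_times_s Blink onsets, seconds.
#' @param seed Integer seed for rendering.
#' @param detection A [detection_config()].
#' @param target_rate_hz Common comparison rate (default 30).
#' @param max_lag_s Alignment search half-width, seconds.
#' @return A list with `agreement` (a `"plr_agreement"`), `measured` and
#'   `truth` percent-change traces (at `target_rate_hz`), and the applied
#'   `lag_s`.
#' @export
simulate_and_validate <- function(params = eye_params(),
                                  dyn = pupil_dynamics(),
                                  protocol = plr_protocol(),
                                  band = spectral_band("far_red"),
                                  blink_times_s = numeric(0),
                                  seed = 1L,
                                  detection = detection_config(),
                                  target_rate_hz = 30,
                                  max_lag_s = 0.5) {
  video <- render_plr_video(params, dyn, protocol, band,
                            blink_times_s = blink_times_s, seed = seed)
  measured <- process_video(video$frames, video$truth$time_s, detection)
  measured <- flag_blink_spikes(measured)
  prep <- function(tr) {
    percent_change_from_mean(downsample_trace(tr, target_rate_hz))
  }
  m30 <- prep(measured)
  t30 <- prep(video$truth)
  pair <- align_traces(t30, m30, max_lag_s = max_lag_s)
  list(agreement = plr_agreement(pair), measured = m30, truth = t30,
       lag_s = pair$lag_s)
}

#' Synthetic validation cohort
#'
#' Runs [simulate_and_validate()] for a cohort of synthetic subjects whose
#' baseline diameter (40-80 px), constriction amplitude (0.15-0.4), iris
#' melanin load (light-blue- to dark-brown-equivalent) and pixel noise
#' (sd 2-5) span the ranges a device-validation study would encounter,
#' each recording containing one blink. The design is a deterministic
#' function of `n_subjects` and `seed`.
#'
#' @param n_subjects Number of synthetic subjects (default 11).
#' @param seed Integer master seed.
#' @return A list with `summary` (a `"validation_summary"`) and `design`
#'   (data frame of per-subject parameters).
#' @export
synthetic_validation_cohort <- function(n_subjects = 11L, seed = 1L) {
  design <- data.frame(
    subject = seq_len(n_subjects),
    baseline_diameter_px = seq(40, 80, length.out = n_subjects),
    constriction_amplitude = seq(0.15, 0.4, length.out = n_subjects),
    melanin_load = seq(melanin_presets[["blue"]],
                       melanin_presets[["dark_brown"]],
                       length.out = n_subjects),
    noise_sd = rep(c(2, 3, 5), length.out = n_subjects),
    blink_time_s = 2.5 + 0.15 * (seq_len(n_subjects) %% 8),
    seed = as.integer((seed + 1000L * seq_len(n_subjects)) %% .Machine$integer.max)
  )
  results <- lapply(seq_len(n_subjects), function(i) {
    d <- design[i, ]
    params <- eye_params(melanin_load = d$melanin_load, noise_sd = d$noise_sd)
    dyn <- pupil_dynamics(baseline_diameter_px = d$baseline_diameter_px,
                          constriction_amplitude = d$constriction_amplitude)
    simulate_and_validate(params = params, dyn = dyn,
                          blink_times_s = d$blink_time_s,
                          seed = d$seed)$agreement
  })
  list(summary = summarize_cohort(results, design$subject), design = design)
}
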