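# Readers and writers for the package's plain-text/PNG interchange
# formats: frame directories with a manifest, trace files, run configs.

#' Write a frame sequence and manifest to a directory
#'
#' Frames are written as zero-padded numbered 8-bit PNG files
#' (`frame_000001.png`, ...) next to a `manifest.csv` with columns
#' `frame_index`, `time_s`, `true_diameter_px`, `blink_flag`,
#' `center_row`, `center_col`. Intensities are quantised from the 0-255
#' double scale to 8 bits on write.
#'
#' @param frames List of frames (matrices or `H x W x 3` arrays, 0-255).
#' @param truth Ground-truth [pupil_trace] with one row per frame.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(frames, truth, dir) {
  if (length(frames) != nrow(truth))
    stopf("truth must have one row per frame")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    png::writePNG(clip01(frames[[i]] / 255),
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  manifest <- data.frame(frame_index = seq_along(frames),
                         time_s = truth$time_s,
                         true_diameter_px = truth$diameter,
                         blink_flag = as.integer(truth$blink),
                         center_row = truth$center_row,
                         center_col = truth$center_col)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a frame directory written by [write_frames()]
#'
#' @param dir Directory containing numbered PNGs and `manifest.csv`.
#' @return A list with `frames` (0-255 doubles) and `truth`
#'   (ground-truth [pupil_trace]).
#' @export
read_frames <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) stopf("no manifest.csv in %s", dir)
  manifest <- utils::read.csv(manifest_path)
  files <- file.path(dir, sprintf("frame_%06d.png", manifest$frame_index))
  missing <- !file.exists(files)
  if (any(missing)) stopf("missing frame file %s", files[which(missing)[1]])
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L && dim(img)[3] > 3L) img <- img[, , 1:3]
    img * 255
  })
  rate <- if (nrow(manifest) > 1) 1 / stats::median(diff(manifest$time_s)) else NA_real_
  truth <- pupil_trace(time_s = manifest$time_s,
                       diameter = manifest$true_diameter_px,
                       blink = manifest$blink_flag > 0,
                       unit = "px", sample_rate_hz = rate,
                       center_row = manifest$center_row,
                       center_col = manifest$center_col)
  list(frames = frames, truth = truth)
}

#' Write a pupil trace to a delimited text file
#'
#' Columns `time_s`, `diameter`, `unit`, `blink_flag` plus any extra
#' columns the trace carries; full precision, comma-separated.
#'
#' @param trace A [pupil_trace].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  out <- data.frame(time_s = df$time_s, diameter = df$diameter,
                    unit = trace_unit(trace),
                    blink_flag = as.integer(df$blink))
  for (nm in setdiff(names(df), c("time_s", "diameter", "blink")))
    out[[nm]] <- df[[nm]]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a pupil trace file
#'
#' @param path File written by [write_trace()] (or any delimited file with
#'   columns `time_s`, `diameter`, `blink_flag`, optionally `unit`).
#' @return A [pupil_trace].
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "diameter", "blink_flag")
  if (!all(need %in% names(df)))
    stopf("trace file needs columns %s", paste(need, collapse = ", "))
  unit <- if ("unit" %in% names(df)) as.character(df$unit[1]) else "px"
  rate <- if (nrow(df) > 1) 1 / stats::median(diff(df$time_s)) else NA_real_
  extra <- df[setdiff(names(df), c("time_s", "diameter", "blink_flag", "unit"))]
  do.call(pupil_trace, c(list(time_s = df$time_s, diameter = df$diameter,
                              blink = df$blink_flag > 0, unit = unit,
                              sample_rate_hz = rate),
                         as.list(extra)))
}

#' Default run configuration
#'
#' The fully-resolved default configuration used by the command-line
#' interface: simulator geometry and dynamics, stimulus protocol, spectral
#' band, detection and analysis settings, and the master seed. Any subset
#' of keys may be overridden from a YAML file; unknown keys are rejected
#' by name.
#'
#' @return Nested list of configuration sections.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    simulator = list(
      image_height_px = 240L, image_width_px = 320L,
      pupil_center = c(120, 160), iris_radius_px = 90,
      sclera_reflectance = 0.85, iris_base_reflectance = 0.8,
      melanin_load = 1, pupil_reflectance = 0.02,
      noise_sd = 3, glare = "default",
      band = "far_red",
      baseline_diameter_px = 60, constriction_amplitude = 0.3,
      latency_s = 0.2, constriction_time_constant_s = 0.15,
      redilation_time_constant_s = 0.7, redilation_fraction = 0.6,
      pre_stimulus_s = 1, stimulus_s = 1, post_stimulus_s = 3,
      frame_rate_hz = 60,
      blink_times_s = numeric(0), blink_width_s = 0.15
    ),
    detection = list(
      downscale = 1L, closing_radius_px = 4L, min_area_px = 50,
      max_area_frac = 0.4, min_circularity = 0.35, min_contrast = 10,
      min_range = 12, hist_smooth_sd = 3
    ),
    analysis = list(
      target_rate_hz = 30, max_lag_s = 0.5,
      blink_spike_threshold = 0.2
    )
  )
}

merge_config <- function(base, override, path = character(0)) {
  for (key in names(override)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base))
      stopf("unknown configuration key: %s", here)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]]))
        stopf("configuration key %s must be a section", here)
      base[[key]] <- merge_config(base[[key]], override[[key]], c(path, key))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Read a YAML run configuration
#'
#' Missing keys fall back to [default_run_config()]; unknown keys raise an
#' error naming the offending key.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @return Fully-resolved configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge_config(cfg, user)
}

#' Write a fully-resolved configuration as YAML
#'
#' Every run writes its resolved configuration next to its outputs so the
#' run can be reproduced from the output directory alone.
#'
#' @param config Configuration list.
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_to_objects <- function(config) {
  s <- config$simulator
  glare <- if (identical(s$glare, "default")) {
    default_glare_spots(s$pupil_center)
  } else if (identical(s$glare, "none") || is.null(s$glare)) {
    NULL
  } else {
    as.data.frame(s$glare)
  }
  list(
    params = eye_params(s$image_height_px, s$image_width_px, s$pupil_center,
                        s$iris_radius_px, s$sclera_reflectance,
                        s$iris_base_reflectance, s$melanin_load,
                        s$pupil_reflectance, glare, s$noise_sd),
    dyn = pupil_dynamics(s$baseline_diameter_px, s$constriction_amplitude,
                         s$latency_s, s$constriction_time_constant_s,
                         s$redilation_time_constant_s, s$redilation_fraction),
    protocol = plr_protocol(s$pre_stimulus_s, s$stimulus_s, s$post_stimulus_s,
                            s$frame_rate_hz),
    band = spectral_band(s$band),
    blink_times_s = as.numeric(s$blink_times_s),
    blink_width_s = s$blink_width_s,
    detection = do.call(detection_config, config$detection)
  )
}
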