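#' Extract the red channel of a frame
#'
#' Far-red imaging concentrates the signal in the red channel, so RGB
#' frames are reduced to grayscale by taking the red channel only.
#' Single-channel frames pass through unchanged.
#'
#' @param frame Matrix (single-channel) or `H x W x 3` RGB array.
#' @return A single-channel matrix.
#' @export
extract_red_channel <- function(frame) {
  nch <- frame_channels(frame)
  if (nch == 1L) return(frame)
  if (nch != 3L) stopf("frame must have 1 or 3 channels, got %d", nch)
  frame[, , 1L]
}

#' Pupil detector configuration
#'
#' Tuning knobs of the classical pupil detector (see [detect_pupil()]).
#' Defaults are sized for frames a few hundred pixels across with pupils
#' of 30-90 px diameter.
#'
#' @param downscale Integer subsampling factor applied before detection
#'   (1 = full resolution); detected centre/diameter are scaled back.
#' @param closing_radius_px Radius of the disc structuring element used to
#'   close glare holes in the binary pupil mask.
#' @param min_area_px Smallest acceptable pupil component area, px^2.
#' @param max_area_frac Largest acceptable component area as a fraction of
#'   the frame.
#' @param min_circularity Minimum circularity `4*pi*A/P^2` of the
#'   component for a detection to be considered valid.
#' @param min_contrast Minimum intensity gap between the component and its
#'   surrounding annulus (8-bit units).
#' @param min_range Minimum frame intensity range; flatter frames are
#'   declared to contain no pupil.
#' @param hist_smooth_sd Gaussian smoothing bandwidth (intensity levels)
#'   for the histogram-valley threshold.
#' @return An object of class `"detection_config"`.
#' @export
detection_config <- function(downscale = 1L, closing_radius_px = 4L,
                             min_area_px = 50, max_area_frac = 0.4,
                             min_circularity = 0.35, min_contrast = 10,
                             min_range = 12, hist_smooth_sd = 3) {
  if (!is_scalar_num(downscale) || downscale < 1 || downscale != round(downscale))
    stopf("`downscale` must be a positive integer")
  structure(list(downscale = as.integer(downscale),
                 closing_radius_px = as.integer(closing_radius_px),
                 min_area_px = min_area_px, max_area_frac = max_area_frac,
                 min_circularity = min_circularity,
                 min_contrast = min_contrast, min_range = min_range,
                 hist_smooth_sd = hist_smooth_sd),
            class = "detection_config")
}

pupil_detection <- function(valid, center = c(NA_real_, NA_real_),
                            diameter_px = NA_real_, confidence = 0) {
  structure(list(valid = valid, center = center, diameter_px = diameter_px,
                 confidence = confidence),
            class = "pupil_detection")
}

#' @export
print.pupil_detection <- function(x, ...) {
  if (!x$valid) {
    cat("Pupil detection: invalid (no pupil found)\n")
  } else {
    cat(sprintf("Pupil detection: center (%.1f, %.1f), diameter %.1f px, confidence %.2f\n",
                x$center[1], x$center[2], x$diameter_px, x$confidence))
  }
  invisible(x)
}

# Threshold at the deepest valley of the smoothed intensity histogram,
# between the two darkest modes. Returns NA when fewer than two modes are
# found (e.g. flat or occluded frames).
histogram_valley_threshold <- function(g, smooth_sd = 3, min_frac = 5e-4,
                                       min_sep = 10) {
  counts <- tabulate(pmin(pmax(round(as.vector(g)), 0), 255) + 1L, 256L)
  w <- max(1L, ceiling(3 * smooth_sd))
  kern <- stats::dnorm(seq(-w, w), sd = smooth_sd)
  kern <- kern / sum(kern)
  padded <- c(rep(0, w), counts, rep(0, w))
  sm <- as.numeric(stats::filter(padded, kern, sides = 2))
  sm <- sm[(w + 1):(w + 256)]
  n <- length(g)
  is_peak <- c(FALSE, diff(sm) > 0) & c(sm[-length(sm)] >= sm[-1], FALSE)
  # include plateau-free local maxima at the very ends
  is_peak[1] <- sm[1] > sm[2]
  is_peak[256] <- sm[256] > sm[255]
  peaks <- which(is_peak & sm >= min_frac * n)
  if (length(peaks) < 2) return(NA_real_)
  # merge peaks closer than min_sep levels, keeping the taller one
  ord <- peaks[order(sm[peaks], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord) if (!length(kept) || all(abs(kept - p) >= min_sep)) kept <- c(kept, p)
  if (length(kept) < 2) return(NA_real_)
  dark2 <- sort(kept)[1:2]
  valley <- which.min(sm[dark2[1]:dark2[2]]) + dark2[1] - 1
  valley - 1  # histogram bin i holds intensity level i-1
}

component_stats <- function(mask, labels, k, g) {
  sel <- labels == k
  idx <- which(sel, arr.ind = TRUE)
  area <- nrow(idx)
  ctr <- colMeans(idx)
  dr <- idx[, 1] - ctr[1]
  dc <- idx[, 2] - ctr[2]
  covm <- matrix(c(mean(dr^2), mean(dr * dc), mean(dr * dc), mean(dc^2)), 2)
  ev <- eigen(covm, symmetric = TRUE)$values
  ev[ev < 1e-9] <- 1e-9
  # for a filled ellipse, variance along a principal axis is (semi-axis)^2/4
  semi_major <- 2 * sqrt(ev[1])
  semi_minor <- 2 * sqrt(ev[2])
  diameter <- 2 * sqrt(semi_major * semi_minor)  # equal-area circle
  # 4-neighbour boundary pixel count as the perimeter estimate
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- sel
  inner <- pad[2:(nr + 1), 2:(nc + 1)]
  nb <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
        pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  perim <- sum(inner & !nb)
  circ <- if (perim > 0) 4 * pi * area / perim^2 else 0
  list(area = area, center = ctr, diameter = diameter,
       circularity = min(1, circ), mean_intensity = mean(g[sel]))
}

#' Detect the pupil in a single frame
#'
#' Classical detector exploiting the high pupil-iris contrast of far-red
#' frames, where the pupil is the darkest compact region by construction:
#' red-channel extraction, optional downscale, a global threshold at the
#' deepest valley of the smoothed intensity histogram between the two
#' darkest modes, morphological closing of the binary mask (in-painting
#' saturated glare specks inside the pupil), largest dark connected
#' component, and a moment-based ellipse fit. The reported diameter is the
#' diameter of the circle with the same area as the fitted ellipse;
#' confidence is the component's circularity `4*pi*A/P^2` clipped to
#' `[0, 1]`.
#'
#' Failure is a state, not an error: frames with no dark quasi-circular
#' region (flat frames, blink-occluded frames) give `valid = FALSE`.
#'
#' @param frame Single- or 3-channel frame (RGB frames are reduced with
#'   [extract_red_channel()]).
#' @param config A [detection_config()].
#' @return A `pupil_detection` with fields `valid`, `center` (row, col),
#'   `diameter_px`, `confidence`.
#' @export
detect_pupil <- function(frame, config = detection_config()) {
  stopifnot(inherits(config, "detection_config"))
  g <- extract_red_channel(frame)
  if (length(g) == 0) stopf("frame is empty")
  k <- config$downscale
  if (k > 1L) g <- g[seq(1L, nrow(g), by = k), seq(1L, ncol(g), by = k), drop = FALSE]
  if (diff(range(g)) < config$min_range) return(pupil_detection(FALSE))
  thr <- histogram_valley_threshold(g, config$hist_smooth_sd)
  if (is.na(thr)) return(pupil_detection(FALSE))
  mask <- g < thr
  brush <- EBImage::makeBrush(2L * config$closing_radius_px + 1L, shape = "disc")
  closed <- EBImage::closing(mask * 1, brush) > 0.5
  labels <- EBImage::bwlabel(closed * 1)
  labels <- matrix(as.integer(labels), nrow(closed), ncol(closed))
  if (max(labels) == 0) return(pupil_detection(FALSE))
  areas <- tabulate(labels[labels > 0])
  best <- which.max(areas)
  st <- component_stats(closed, labels, best, g)
  if (st$area < config$min_area_px / k^2 ||
      st$area > config$max_area_frac * length(g) ||
      st$circularity < config$min_circularity)
    return(pupil_detection(FALSE))
  # contrast check against the surrounding annulus
  nr <- nrow(g); nc <- ncol(g)
  rr <- matrix(seq_len(nr), nr, nc) - st$center[1]
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - st$center[2]
  dist <- sqrt(rr^2 + cc^2)
  req <- st$diameter / 2
  ring <- dist > 1.15 * req & dist < 1.6 * req
  if (sum(ring) >= 20) {
    if (stats::median(g[ring]) - st$mean_intensity < config$min_contrast)
      return(pupil_detection(FALSE))
  }
  pupil_detection(TRUE,
                  center = unname((st$center - 1) * k + 1),
                  diameter_px = st$diameter * k,
                  confidence = st$circularity)
}

#' Convert a frame sequence into a pupil diameter trace
#'
#' Runs [detect_pupil()] on every frame; samples whose detection is
#' invalid (occlusions, flat frames) are flagged as blinks. Centre and
#' confidence are carried per sample.
#'
#' @param frames List of frames.
#' @param timestamps_s Per-frame timestamps, strictly increasing.
#' @param config A [detection_config()].
#' @return A [pupil_trace] (unit `"px"`) of the same length as `frames`,
#'   with columns `time_s`, `diameter`, `blink`, `center_row`,
#'   `center_col`, `confidence`.
#' @export
process_video <- function(frames, timestamps_s, config = detection_config()) {
  if (!length(frames)) stopf("no frames supplied")
  if (length(timestamps_s) != length(frames))
    stopf("timestamps and frames differ in length")
  n <- length(frames)
  diameter <- rep(NA_real_, n)
  blink <- rep(FALSE, n)
  crow <- rep(NA_real_, n); ccol <- rep(NA_real_, n)
  conf <- rep(0, n)
  for (i in seq_len(n)) {
    det <- detect_pupil(frames[[i]], config)
    if (det$valid) {
      diameter[i] <- det$diameter_px
      crow[i] <- det$center[1]; ccol[i] <- det$center[2]
      conf[i] <- det$confidence
    } else {
      blink[i] <- TRUE
    }
  }
  # carry the last valid diameter through flagged samples so the trace stays
  # numeric; flagged samples are excluded from every downstream statistic
  if (all(is.na(diameter))) stopf("no valid pupil detection in any frame")
  filled <- diameter
  last <- filled[which(!is.na(filled))[1]]
  for (i in seq_len(n)) {
    if (is.na(filled[i])) filled[i] <- last else last <- filled[i]
  }
  rate <- if (n > 1) 1 / stats::median(diff(timestamps_s)) else NA_real_
  pupil_trace(time_s = timestamps_s, diameter = filled, blink = blink,
              unit = "px", sample_rate_hz = rate,
              center_row = crow, center_col = ccol, confidence = conf)
}
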