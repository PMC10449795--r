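#' A 15 x 15 pixel block
#'
#' The contrast statistic compares two square blocks of 225 representative
#' pixels, one centred in the pupil and one on the iris.
#'
#' @param top_left `(row, col)` of the block's top-left pixel.
#' @param size Block side length in pixels (default 15).
#' @param label `"pupil"` or `"iris"`.
#' @return An object of class `"pixel_block"`.
#' @export
pixel_block <- function(top_left, size = 15L, label = c("pupil", "iris")) {
  label <- match.arg(label)
  if (length(top_left) != 2L || any(!is.finite(top_left)))
    stopf("`top_left` must be (row, col)")
  structure(list(top_left = as.integer(round(top_left)),
                 size = as.integer(size), label = label),
            class = "pixel_block")
}

block_in_frame <- function(block, nrow_frame, ncol_frame) {
  tl <- block$top_left
  tl[1] >= 1 && tl[2] >= 1 &&
    tl[1] + block$size - 1 <= nrow_frame &&
    tl[2] + block$size - 1 <= ncol_frame
}

block_centered_at <- function(center, size = 15L, label = "pupil") {
  half <- (size - 1) / 2
  pixel_block(round(center) - half, size = size, label = label)
}

#' Pixel values of a block
#'
#' @param frame Single-channel frame.
#' @param block A [pixel_block()].
#' @return Numeric vector of the block's pixel intensities
#'   (`size^2` values).
#' @export
block_values <- function(frame, block) {
  if (frame_channels(frame) != 1L)
    stopf("`frame` must be single-channel; extract the red channel first")
  if (!block_in_frame(block, nrow(frame), ncol(frame)))
    stopf("block does not lie fully inside the frame")
  tl <- block$top_left
  as.vector(frame[tl[1]:(tl[1] + block$size - 1), tl[2]:(tl[2] + block$size - 1)])
}

#' Select pupil and iris pixel blocks
#'
#' Places a block of `block_size^2` pixels at the pupil centre and a
#' matching iris block at twice the pupil radius from the centre along a
#' 45-degree diagonal. Glare avoidance is automated: among the four
#' diagonal candidates (45, 135, 225, 315 degrees from image-horizontal,
#' upper-right first), the block with the smallest within-block intensity
#' variance is chosen; if every in-frame candidate contains saturated
#' pixels, the candidates are shifted radially by +/- 0.25 pupil radius
#' and re-evaluated.
#'
#' @param frame Single-channel frame (red channel).
#' @param detection A valid `pupil_detection`.
#' @param block_size Block side length, px (default 15).
#' @param distance_factor Iris block distance from the pupil centre in
#'   units of the pupil radius (default 2).
#' @param saturation_level Intensity at or above which a pixel counts as
#'   saturated glare (default 250).
#' @return A list with elements `pupil` and `iris`, both [pixel_block()]s.
#' @export
select_pixel_blocks <- function(frame, detection, block_size = 15L,
                                distance_factor = 2, saturation_level = 250) {
  if (!inherits(detection, "pupil_detection") || !detection$valid)
    stopf("`detection` must be a valid pupil detection")
  if (frame_channels(frame) != 1L)
    stopf("`frame` must be single-channel; extract the red channel first")
  ctr <- detection$center
  r <- detection$diameter_px / 2
  pupil <- block_centered_at(ctr, block_size, "pupil")
  if (!block_in_frame(pupil, nrow(frame), ncol(frame)))
    stopf("pupil block does not fit inside the frame")
  u <- 1 / sqrt(2)
  # (row, col) unit vectors: upper-right, upper-left, lower-left, lower-right
  dirs <- rbind(c(-u, u), c(-u, -u), c(u, -u), c(u, u))
  candidates_at <- function(dist) {
    lapply(seq_len(nrow(dirs)), function(i)
      block_centered_at(ctr + dist * dirs[i, ], block_size, "iris"))
  }
  eval_set <- function(cands) {
    cands <- Filter(function(b) block_in_frame(b, nrow(frame), ncol(frame)), cands)
    if (!length(cands)) return(NULL)
    vals <- lapply(cands, function(b) block_values(frame, b))
    list(cands = cands,
         variance = vapply(vals, stats::var, numeric(1)),
         saturated = vapply(vals, function(v) any(v >= saturation_level), logical(1)))
  }
  pick <- function(ev) {
    if (is.null(ev)) return(NULL)
    ok <- which(!ev$saturated)
    if (length(ok)) ev$cands[[ok[which.min(ev$variance[ok])]]] else NULL
  }
  ev0 <- eval_set(candidates_at(distance_factor * r))
  if (is.null(ev0)) stopf("no iris block candidate fits inside the frame")
  iris <- pick(ev0)
  if (is.null(iris)) {
    for (dist in (distance_factor + c(0.25, -0.25)) * r) {
      iris <- pick(eval_set(candidates_at(dist)))
      if (!is.null(iris)) break
    }
  }
  if (is.null(iris)) iris <- ev0$cands[[which.min(ev0$variance)]]
  list(pupil = pupil, iris = iris)
}

#' Pupil-iris contrast of a frame
#'
#' The contrast is the difference in pixel intensity between the iris and
#' the pupil: `iris_intensity - pupil_intensity`, where each intensity is
#' a block statistic (mean by default; the median alternative is provided
#' as a configuration switch) over the 225 pixels of the corresponding
#' block.
#'
#' @param frame Single-channel frame (red channel already extracted).
#' @param pupil_block,iris_block [pixel_block()]s, e.g. from
#'   [select_pixel_blocks()].
#' @param statistic `"mean"` (default) or `"median"`.
#' @param condition Optional spectral-condition label
#'   (`"far_red"`/`"full_visible"`).
#' @param device Optional device label.
#' @return An object of class `"contrast_measurement"` with fields
#'   `pupil_intensity`, `iris_intensity`, `contrast`, `condition`,
#'   `device`.
#' @export
pupil_iris_contrast <- function(frame, pupil_block, iris_block,
                                statistic = c("mean", "median"),
                                condition = NA_character_,
                                device = NA_character_) {
  statistic <- match.arg(statistic)
  if (frame_channels(frame) != 1L)
    stopf("`frame` must be single-channel; extract the red channel first")
  stat_fun <- if (statistic == "mean") mean else stats::median
  pup <- stat_fun(block_values(frame, pupil_block))
  iri <- stat_fun(block_values(frame, iris_block))
  structure(list(pupil_intensity = pup, iris_intensity = iri,
                 contrast = iri - pup, condition = condition, device = device),
            class = "contrast_measurement")
}

#' @export
print.contrast_measurement <- function(x, ...) {
  cat(sprintf("Pupil-iris contrast: %.1f (iris %.1f - pupil %.1f)",
              x$contrast, x$iris_intensity, x$pupil_intensity))
  if (!is.na(x$condition)) cat("  [", x$condition, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Contrast percent increase between spectral conditions
#'
#' The headline comparison of far-red against full-visible imaging:
#' `100 * (contrast_far_red - contrast_full) / |contrast_full|`. The
#' absolute value in the denominator preserves the direction of the change
#' when the full-visible contrast is negative; the result may itself be
#' negative.
#'
#' @param contrast_far_red,contrast_full Contrast values (8-bit intensity
#'   units), scalars or equal-length vectors; `contrast_full` must be
#'   nonzero.
#' @return Percent increase (may be negative).
#' @export
contrast_percent_increase <- function(contrast_far_red, contrast_full) {
  if (any(contrast_full == 0))
    stopf("percent increase is undefined when the full-visible contrast is zero")
  100 * (contrast_far_red - contrast_full) / abs(contrast_full)
}

#' Convert sRGB pixels to CIELAB
#'
#' Standard-formula conversion: the official sRGB transfer function, the
#' sRGB-to-XYZ matrix, and the CIE L*a*b* transform under the D65 white
#' point (2-degree observer). Pure white maps to L* = 100 and pure black
#' to L* = 0 exactly.
#'
#' @param rgb Numeric matrix with 3 columns (R, G, B) on the 0-255 scale,
#'   or a vector of length 3.
#' @return Matrix with columns `L`, `a`, `b`.
#' @export
srgb_to_lab <- function(rgb) {
  if (is.null(dim(rgb))) rgb <- matrix(rgb, ncol = 3)
  if (ncol(rgb) != 3) stopf("`rgb` must have 3 columns")
  u <- rgb / 255
  lin <- ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(m)
  # D65 white as the image of (1, 1, 1) under the same matrix, so that
  # pure white maps to L* = 100 exactly
  white <- as.numeric(m %*% rep(1, 3))
  xyz <- sweep(xyz, 2, white, "/")
  eps <- (6 / 29)^3
  f <- ifelse(xyz > eps, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  out <- cbind(L = 116 * f[, 2] - 16,
               a = 500 * (f[, 1] - f[, 2]),
               b = 200 * (f[, 2] - f[, 3]))
  out
}

#' Iris luminance from an RGB frame
#'
#' Quantifies iris colour as the median CIELAB L* over a 15 x 15 iris
#' block, the block-median convention used for characterising participant
#' eye colour. The qualitative eye-colour label is an input (self-assessed
#' in practice), never inferred from L*.
#'
#' @param frame `H x W x 3` RGB frame on the 0-255 scale.
#' @param iris_block A [pixel_block()] on the iris.
#' @param eye_color_label Optional label (`"blue"`, `"light_brown"`,
#'   `"dark_brown"`).
#' @return An object of class `"iris_color_record"` with fields
#'   `iris_luminance` (median L*, 0-100) and `eye_color_label`.
#' @export
iris_luminance <- function(frame, iris_block, eye_color_label = NA_character_) {
  if (frame_channels(frame) != 3L)
    stopf("`frame` must be a 3-channel RGB array")
  tl <- iris_block$top_left
  rows <- tl[1]:(tl[1] + iris_block$size - 1)
  cols <- tl[2]:(tl[2] + iris_block$size - 1)
  if (min(rows) < 1 || min(cols) < 1 ||
      max(rows) > dim(frame)[1] || max(cols) > dim(frame)[2])
    stopf("block does not lie fully inside the frame")
  px <- cbind(as.vector(frame[rows, cols, 1]),
              as.vector(frame[rows, cols, 2]),
              as.vector(frame[rows, cols, 3]))
  lab <- srgb_to_lab(px)
  structure(list(iris_luminance = stats::median(lab[, "L"]),
                 eye_color_label = eye_color_label),
            class = "iris_color_record")
}

#' @export
print.iris_color_record <- function(x, ...) {
  cat(sprintf("Iris luminance L* = %.1f", x$iris_luminance))
  if (!is.na(x$eye_color_label)) cat("  (", x$eye_color_label, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Cross-device summary of contrast percent increases
#'
#' Aggregates per-participant, per-device contrast percent increases into
#' the cross-phone comparison layout: per participant, the mean and sample
#' standard deviation across devices; at cohort level, the grand mean of
#' the per-participant means, overall and restricted to each eye-colour
#' label. Participants measured on a single device report an undefined
#' (NA) standard deviation.
#'
#' @param data Data frame with columns `participant`, `device`,
#'   `percent_increase` and optionally `eye_color`.
#' @return An object of class `"cross_device_table"`: list with
#'   `per_participant` (data frame), `grand_mean`, and `grand_mean_by_color`
#'   (named vector).
#' @export
cross_device_table <- function(data) {
  data <- as.data.frame(data)
  need <- c("participant", "device", "percent_increase")
  if (!all(need %in% names(data)))
    stopf("`data` needs columns %s", paste(need, collapse = ", "))
  if (nrow(data) == 0) stopf("`data` is empty")
  if (!"eye_color" %in% names(data)) data$eye_color <- NA_character_
  ids <- unique(data$participant)
  per <- do.call(rbind, lapply(ids, function(id) {
    d <- data[data$participant == id, ]
    data.frame(participant = id,
               eye_color = d$eye_color[1],
               n_devices = nrow(d),
               mean = mean(d$percent_increase),
               sd = if (nrow(d) > 1) stats::sd(d$percent_increase) else NA_real_)
  }))
  by_color <- tapply(per$mean, per$eye_color, mean)
  structure(list(per_participant = per,
                 grand_mean = mean(per$mean),
                 grand_mean_by_color = by_color),
            class = "cross_device_table")
}

#' @export
print.cross_device_table <- function(x, ...) {
  cat("Cross-device contrast percent increase\n")
  per <- x$per_participant
  per$mean <- round(per$mean, 1)
  per$sd <- round(per$sd, 1)
  print(per, row.names = FALSE)
  cat(sprintf("Grand mean: %.1f%%\n", x$grand_mean))
  if (any(!is.na(names(x$grand_mean_by_color)))) {
    for (lab in names(x$grand_mean_by_color))
      cat(sprintf("  %s: %.1f%%\n", lab, x$grand_mean_by_color[[lab]]))
  }
  invisible(x)
}
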