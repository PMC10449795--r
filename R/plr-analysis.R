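#' Pupil diameter time series
#'
#' Container for a pupillometry trace: timestamps, diameters, per-sample
#' blink flags, plus the diameter unit (`"px"` for camera-based traces,
#' `"mm"` for reference pupillometer traces, `"percent"` after
#' normalisation) and sample rate carried as attributes. Units are never
#' mixed: agreement statistics operate on percent-change traces only.
#'
#' @param time_s Strictly increasing timestamps, seconds.
#' @param diameter Diameter values (unit as given).
#' @param blink Logical blink/exclusion flags.
#' @param unit `"px"`, `"mm"` or `"percent"`.
#' @param sample_rate_hz Nominal sample rate.
#' @param ... Additional equal-length columns (e.g. `center_row`,
#'   `center_col`, `confidence`).
#' @return A data frame of class `"pupil_trace"`.
#' @export
pupil_trace <- function(time_s, diameter, blink = rep(FALSE, length(time_s)),
                        unit = "px", sample_rate_hz = NA_real_, ...) {
  n <- length(time_s)
  if (length(diameter) != n || length(blink) != n)
    stopf("time_s, diameter and blink must have equal lengths")
  if (n > 1 && any(diff(time_s) <= 0))
    stopf("timestamps must be strictly increasing")
  extra <- list(...)
  if (length(extra) && any(vapply(extra, length, 1L) != n))
    stopf("all trace columns must have equal lengths")
  df <- data.frame(time_s = time_s, diameter = diameter,
                   blink = as.logical(blink))
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  structure(df, unit = unit, sample_rate_hz = sample_rate_hz,
            class = c("pupil_trace", "data.frame"))
}

trace_unit <- function(trace) attr(trace, "unit")

trace_rate <- function(trace) attr(trace, "sample_rate_hz")

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf("Pupil trace: %d samples at %s Hz, unit %s, %d blink-flagged\n",
              nrow(x), format(trace_rate(x)), trace_unit(x), sum(x$blink)))
  NextMethod()
}

#' @export
plot.pupil_trace <- function(x, ...) {
  ylab <- switch(trace_unit(x), px = "diameter (px)", mm = "diameter (mm)",
                 percent = "change from mean (%)", "diameter")
  graphics::plot(x$time_s, x$diameter, type = "l", xlab = "time (s)",
                 ylab = ylab, ...)
  if (any(x$blink))
    graphics::points(x$time_s[x$blink], x$diameter[x$blink],
                     col = "red", pch = 4)
  invisible(x)
}

#' Downsample a trace to a lower rate
#'
#' Reduces e.g. a 60 Hz smartphone trace to the 30 Hz rate of a reference
#' pupillometer. The source rate must be an integer multiple of the target
#' rate. The default kernel is the mean over each window of consecutive
#' samples (noise-suppressing); `method = "decimate"` keeps the first
#' sample of each window instead. A window containing any blink-flagged
#' sample is blink-flagged. A trailing partial window is dropped.
#'
#' @param trace A [pupil_trace].
#' @param target_rate_hz Target rate (default 30).
#' @param method `"mean"` (default) or `"decimate"`.
#' @return A [pupil_trace] at the target rate.
#' @export
downsample_trace <- function(trace, target_rate_hz = 30,
                             method = c("mean", "decimate")) {
  method <- match.arg(method)
  rate <- trace_rate(trace)
  if (!is.finite(rate)) stopf("trace has no sample rate")
  factor <- rate / target_rate_hz
  if (abs(factor - round(factor)) > 1e-8)
    stopf("source rate (%g Hz) is not an integer multiple of %g Hz",
          rate, target_rate_hz)
  factor <- as.integer(round(factor))
  if (factor == 1L) return(trace)
  n_out <- nrow(trace) %/% factor
  idx <- rep(seq_len(n_out), each = factor)
  head_n <- n_out * factor
  grp <- function(v, fun) as.numeric(tapply(v[seq_len(head_n)], idx, fun))
  d <- if (method == "mean") grp(trace$diameter, mean)
       else trace$diameter[seq(1, head_n, by = factor)]
  pupil_trace(time_s = grp(trace$time_s, mean),
              diameter = d,
              blink = as.logical(grp(trace$blink, any)),
              unit = trace_unit(trace), sample_rate_hz = target_rate_hz)
}

#' Percent change from mean
#'
#' Normalises a diameter trace to `100 * (d - dbar) / dbar`, where `dbar`
#' is the mean diameter over non-excluded (non-blink) samples. The result
#' is unit-free, making pixel-based and millimetre-based traces directly
#' comparable; scaling the input by any positive constant leaves the
#' output unchanged. Blink-flagged samples receive values too but stay
#' flagged, so they never enter downstream statistics.
#'
#' @param trace A [pupil_trace] in `"px"` or `"mm"`.
#' @return A [pupil_trace] with unit `"percent"`.
#' @export
percent_change_from_mean <- function(trace) {
  keep <- !trace$blink
  if (!any(keep)) stopf("all samples are blink-excluded")
  dbar <- mean(trace$diameter[keep])
  if (!is.finite(dbar) || dbar <= 0)
    stopf("mean diameter over non-excluded samples must be positive")
  out <- trace
  out$diameter <- 100 * (trace$diameter - dbar) / dbar
  attr(out, "unit") <- "percent"
  out
}

#' Flag dropout spikes as blinks
#'
#' Camera-based traces lack a hardware blink detector; partial occlusions
#' can slip through as implausible diameter excursions. A sample is
#' flagged when its diameter deviates from the median of its `window`
#' nearest neighbours by more than `threshold` times that local median.
#'
#' @param trace A [pupil_trace].
#' @param threshold Relative deviation triggering a flag (default 0.2).
#' @param window Neighbourhood size, odd (default 5).
#' @return The trace with spike samples additionally blink-flagged.
#' @export
flag_blink_spikes <- function(trace, threshold = 0.2, window = 5L) {
  n <- nrow(trace)
  if (n < window) return(trace)
  half <- window %/% 2L
  d <- trace$diameter
  spike <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    ref <- stats::median(d[setdiff(lo:hi, i)])
    if (is.finite(ref) && ref > 0 && abs(d[i] - ref) > threshold * ref)
      spike[i] <- TRUE
  }
  trace$blink <- trace$blink | spike
  trace
}

#' Align two percent-change traces by cross-correlation
#'
#' Device recordings started by simultaneous button press can be offset by
#' a fraction of a second; alignment is automated by scanning integer-
#' sample lags in `[-max_lag_s, max_lag_s]` and maximising the Pearson
#' correlation over the jointly non-excluded overlap (ties broken toward
#' the smallest absolute lag). The reported `lag_s` is the time advance
#' applied to `b`: positive when `b` trails `a`.
#'
#' @param a,b [pupil_trace]s in `"percent"` at the same sample rate.
#' @param max_lag_s Maximum absolute lag, seconds (default 0.5; 0 compares
#'   the traces as-is).
#' @return An object of class `"aligned_pair"`: list with `a`, `b`
#'   (overlap-truncated equal-length vectors), `time_s`, `mask` (joint
#'   non-blink mask), `lag_s`, `lag_samples`.
#' @export
align_traces <- function(a, b, max_lag_s = 0.5) {
  if (trace_unit(a) != "percent" || trace_unit(b) != "percent")
    stopf("both traces must be percent-change traces")
  rate <- trace_rate(a)
  if (!isTRUE(all.equal(rate, trace_rate(b))))
    stopf("traces must share a sample rate")
  if (max_lag_s < 0) stopf("`max_lag_s` must be nonnegative")
  max_lag <- as.integer(round(max_lag_s * rate))
  na <- nrow(a); nb <- nrow(b)
  best <- NULL
  for (lag in -max_lag:max_lag) {
    # match a[i] with b[i + lag]
    i_a <- seq_len(na)
    i_b <- i_a + lag
    ok <- i_b >= 1 & i_b <= nb
    i_a <- i_a[ok]; i_b <- i_b[ok]
    if (!length(i_a)) next
    mask <- !a$blink[i_a] & !b$blink[i_b]
    if (sum(mask) < 10) next
    va <- a$diameter[i_a][mask]; vb <- b$diameter[i_b][mask]
    r <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) -Inf
         else stats::cor(va, vb)
    if (is.null(best) || r > best$r + 1e-12 ||
        (abs(r - best$r) <= 1e-12 && abs(lag) < abs(best$lag))) {
      best <- list(lag = lag, r = r, i_a = i_a, i_b = i_b, mask = mask)
    }
  }
  if (is.null(best))
    stopf("fewer than 10 jointly non-excluded samples at every lag")
  structure(list(a = a$diameter[best$i_a], b = b$diameter[best$i_b],
                 time_s = a$time_s[best$i_a], mask = best$mask,
                 lag_s = best$lag / rate, lag_samples = best$lag,
                 sample_rate_hz = rate),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("Aligned trace pair: %d overlapping samples (%d excluded), lag %.3f s\n",
              length(x$a), sum(!x$mask), x$lag_s))
  invisible(x)
}

#' Apply the joint blink-exclusion mask
#'
#' A sample flagged as a blink in either trace is excluded from both, so
#' camera dropouts and reference-device blink detections remove the same
#' time points from every downstream statistic.
#'
#' @param pair An `"aligned_pair"` from [align_traces()].
#' @return The pair with excluded samples removed (`mask` all `TRUE`,
#'   `n_excluded` recording how many were dropped).
#' @export
exclude_blinks <- function(pair) {
  stopifnot(inherits(pair, "aligned_pair"))
  keep <- pair$mask
  out <- pair
  out$a <- pair$a[keep]
  out$b <- pair$b[keep]
  out$time_s <- pair$time_s[keep]
  out$mask <- rep(TRUE, sum(keep))
  out$n_excluded <- sum(!keep)
  out
}
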