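#' Mean absolute error
#'
#' @param a,b Equal-length numeric vectors.
#' @return `mean(|a - b|)`.
#' @export
mae <- function(a, b) {
  if (length(a) != length(b)) stopf("`a` and `b` must have equal lengths")
  if (!length(a)) stopf("empty input")
  mean(abs(a - b))
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] that rejects degenerate inputs
#' distinctly: constant vectors have no defined correlation.
#'
#' @param a,b Equal-length numeric vectors, length >= 3, nonconstant.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stopf("`a` and `b` must have equal lengths")
  if (length(a) < 3) stopf("need at least 3 paired samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stopf("correlation is undefined for constant input")
  stats::cor(a, b)
}

#' Bland-Altman agreement analysis
#'
#' Pairwise differences `d_i = a_i - b_i`: bias is their mean, the limits
#' of agreement are `bias +/- 1.96 * sd(d)` with the sample (n-1)
#' standard deviation. Per-pair means and differences are returned for
#' plotting.
#'
#' @param a,b Equal-length numeric vectors, length >= 2.
#' @return An object of class `"bland_altman"`: list with `bias`,
#'   `loa_low`, `loa_high`, `sd_diff`, `means`, `diffs`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stopf("`a` and `b` must have equal lengths")
  if (length(a) < 2) stopf("need at least 2 paired samples")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s,
                 means = (a + b) / 2, diffs = d, n = length(a)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, limits of agreement [%.3f, %.3f], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "mean of pair",
                 ylab = "difference (a - b)", ...)
  graphics::abline(h = c(x$loa_low, x$bias, x$loa_high),
                   lty = c(2, 1, 2), col = c("red", "black", "red"))
  invisible(x)
}

#' Agreement between two paired percent-change traces
#'
#' Bundles the per-subject device-agreement statistics computed on
#' blink-excluded, aligned percent-change samples: mean absolute error (in
#' percentage points), Pearson correlation, and Bland-Altman bias with
#' 1.96-SD limits of agreement.
#'
#' @param pair An `"aligned_pair"` (see [align_traces()]), or a numeric
#'   vector (with `b` supplied).
#' @param b Second vector when `pair` is a vector.
#' @return An object of class `"plr_agreement"`: list with `mae_pct`,
#'   `pearson_r`, `bias`, `loa_low`, `loa_high`, `n_samples`.
#' @export
plr_agreement <- function(pair, b = NULL) {
  if (inherits(pair, "aligned_pair")) {
    pair <- exclude_blinks(pair)
    a <- pair$a; b <- pair$b
  } else {
    a <- pair
    if (is.null(b)) stopf("supply an aligned pair or two vectors")
  }
  ba <- bland_altman(a, b)
  structure(list(mae_pct = mae(a, b), pearson_r = pearson(a, b),
                 bias = ba$bias, loa_low = ba$loa_low,
                 loa_high = ba$loa_high, n_samples = length(a)),
            class = "plr_agreement")
}

#' @export
print.plr_agreement <- function(x, ...) {
  cat(sprintf(
    "PLR agreement: MAE %.2f pp, Pearson r %.3f, bias %.2f [%.2f, %.2f], n = %d\n",
    x$mae_pct, x$pearson_r, x$bias, x$loa_low, x$loa_high, x$n_samples))
  invisible(x)
}

#' Cohort summary of per-subject agreement
#'
#' Arithmetic mean and sample SD of the per-subject MAE values, and the
#' mean of the per-subject Pearson correlations.
#'
#' @param results List of `"plr_agreement"` objects.
#' @param subject_ids Optional subject labels.
#' @return An object of class `"validation_summary"`: list with
#'   `per_subject` (data frame), `cohort_mean_mae`, `cohort_sd_mae`,
#'   `cohort_mean_r`.
#' @export
summarize_cohort <- function(results, subject_ids = seq_along(results)) {
  if (!length(results)) stopf("no subjects supplied")
  per <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(subject = subject_ids[i], n_samples = r$n_samples,
               mae_pct = r$mae_pct, pearson_r = r$pearson_r,
               ba_bias = r$bias, ba_loa_low = r$loa_low,
               ba_loa_high = r$loa_high)
  }))
  structure(list(per_subject = per,
                 cohort_mean_mae = mean(per$mae_pct),
                 cohort_sd_mae = if (nrow(per) > 1) stats::sd(per$mae_pct) else NA_real_,
                 cohort_mean_r = mean(per$pearson_r)),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("Validation cohort (N = %d): mean MAE %.2f pp (SD %.2f), mean r %.3f\n",
              nrow(x$per_subject), x$cohort_mean_mae,
              x$cohort_sd_mae, x$cohort_mean_r))
  per <- x$per_subject
  per[-1] <- lapply(per[-1], function(v) round(v, 3))
  print(per, row.names = FALSE)
  invisible(x)
}
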