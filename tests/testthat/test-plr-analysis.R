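test_that("downsampling halves the rate with pairwise means and blink propagation", {
  tr <- make_trace(c(4, 4, 6, 6), rate = 60)
  out <- downsample_trace(tr, 30)
  expect_equal(out$diameter, c(4, 6))
  expect_equal(attr(out, "sample_rate_hz"), 30)

  const <- downsample_trace(make_trace(rep(5, 60)), 30)
  expect_true(all(const$diameter == 5))

  tr300 <- make_trace(seq(60, 40, length.out = 300))
  expect_equal(nrow(downsample_trace(tr300, 30)), 150)

  # any blink inside a window flags the window
  trb <- make_trace(rep(5, 6), blink = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(downsample_trace(trb, 30)$blink, c(TRUE, FALSE, TRUE))

  # decimation keeps the first sample of each window
  expect_equal(downsample_trace(make_trace(c(4, 5, 6, 7)), 30,
                                method = "decimate")$diameter, c(4, 6))

  expect_error(downsample_trace(make_trace(rep(1, 10), rate = 50), 30),
               "integer multiple")
})

test_that("percent change from mean is centred, scale-free and blink-aware", {
  expect_equal(percent_change_from_mean(make_trace(c(4, 4, 4, 4)))$diameter,
               rep(0, 4))
  expect_equal(percent_change_from_mean(make_trace(c(3, 5)))$diameter,
               c(-25, 25))

  set.seed(7)
  d <- stats::runif(50, 40, 60)
  p1 <- percent_change_from_mean(make_trace(d))$diameter
  p2 <- percent_change_from_mean(make_trace(d * 3.7, unit = "mm"))$diameter
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(mean(p1), 0, tolerance = 1e-10)

  # the reference mean ignores blink-flagged samples
  bl <- c(rep(FALSE, 49), TRUE)
  d2 <- c(rep(10, 49), 1000)
  pb <- percent_change_from_mean(make_trace(d2, blink = bl))
  expect_equal(pb$diameter[1], 0)

  expect_error(percent_change_from_mean(
    make_trace(c(1, 2), blink = c(TRUE, TRUE))), "excluded")
})

test_that("downsample and percent-change commute on blink-free traces", {
  set.seed(11)
  d <- 50 + cumsum(stats::rnorm(300, 0, 0.3))
  tr <- make_trace(d)
  a <- percent_change_from_mean(downsample_trace(tr, 30))$diameter
  b <- downsample_trace(percent_change_from_mean(tr), 30)$diameter
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("cross-correlation alignment recovers constructed lags", {
  d <- 50 - 10 * exp(-(seq(0, 5, by = 1 / 30) - 1.2)^2 / 0.3)
  pa <- percent_change_from_mean(make_trace(d, rate = 30))
  expect_equal(align_traces(pa, pa, max_lag_s = 0.5)$lag_samples, 0)

  # b delayed by 3 samples: b[i] = a[i - 3]
  db <- c(rep(d[1], 3), d[seq_len(length(d) - 3)])
  pb <- percent_change_from_mean(make_trace(db, rate = 30))
  al <- align_traces(pa, pb, max_lag_s = 0.5)
  expect_equal(al$lag_samples, 3)
  expect_equal(al$lag_s, 0.1)

  # with max_lag 0 the traces are compared as-is
  expect_equal(align_traces(pa, pb, max_lag_s = 0)$lag_samples, 0)

  # blink masks that never jointly clear 10 samples: error
  pblink <- percent_change_from_mean(make_trace(d, rate = 30))
  pblink$blink <- rep(TRUE, nrow(pa))
  expect_error(align_traces(pa, pblink, max_lag_s = 0.2), "10")
})

test_that("joint blink exclusion removes the union mask from both traces", {
  set.seed(17)
  d <- 50 + stats::rnorm(40)
  mka <- rep(FALSE, 40); mka[1:10] <- TRUE
  mkb <- rep(FALSE, 40); mkb[31:40] <- TRUE
  pa <- percent_change_from_mean(make_trace(d, rate = 30, blink = mka))
  pb <- percent_change_from_mean(make_trace(d + 1, rate = 30, blink = mkb))
  al <- align_traces(pa, pb, max_lag_s = 0)
  ex <- exclude_blinks(al)
  expect_equal(length(ex$a), 40 - sum(mka | mkb))
  expect_equal(ex$n_excluded, sum(mka | mkb))
  expect_equal(length(ex$a), length(ex$b))

  # no blinks anywhere: nothing removed
  pa0 <- percent_change_from_mean(make_trace(d, rate = 30))
  al0 <- align_traces(pa0, pa0, max_lag_s = 0)
  expect_equal(exclude_blinks(al0)$n_excluded, 0)
})

test_that("dropout spikes are flagged as blinks", {
  d <- rep(50, 30); d[15] <- 20
  tr <- flag_blink_spikes(make_trace(d))
  expect_true(tr$blink[15])
  expect_equal(sum(tr$blink), 1)
  smooth <- flag_blink_spikes(make_trace(seq(50, 45, length.out = 30)))
  expect_false(any(smooth$blink))
})

test_that("trace container enforces its invariants", {
  expect_error(pupil_trace(c(0, 0.1), c(1, 2, 3)), "equal lengths")
  expect_error(pupil_trace(c(0.2, 0.1), c(1, 2)), "increasing")
})
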