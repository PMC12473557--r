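test_that("resampling a 2 Hz sine from 75 to 64 Hz stays within 1% of the analytic signal", {
  t75 <- (0:(75 * 30 - 1)) / 75
  ch <- ts_channel("WIRED_PPG", sin(2 * pi * 2 * t75), rate = 75)
  out <- resample_channel(ch, 64)
  expect_equal(out$rate, 64)
  t64 <- channel_times(out)
  err <- abs(out$values - sin(2 * pi * 2 * t64))
  expect_lt(max(err, na.rm = TRUE), 0.01)
})

test_that("resampling at the current rate is the identity", {
  ch <- ts_channel("WIRELESS_PPG", rnorm(640), rate = 64)
  expect_identical(resample_channel(ch, 64), ch)
})

test_that("no values are synthesized inside a missing run", {
  t75 <- (0:(75 * 30 - 1)) / 75
  v <- sin(2 * pi * 2 * t75)
  v[751:825] <- NA   # 1 s missing starting at t = 10
  out <- resample_channel(ts_channel("WIRED_PPG", v, rate = 75), 64)
  t64 <- channel_times(out)
  expect_true(all(is.na(out$values[t64 >= 10 & t64 < 11])))
  expect_true(all(!is.na(out$values[t64 >= 2 & t64 < 9])))
})

test_that("SpO2 resampling uses nearest neighbour within half a sample, else missing", {
  ch <- ts_channel("WIRED_SPO2", c(95, 96, NA, 98), rate = 1)
  out <- resample_channel(ch, 2)
  expect_equal(out$rate, 2)
  # 2 Hz grid: 0.0, 0.5, 1.0, ... ; 0.5 is exactly at the window edge of both
  expect_equal(out$values[1], 95)
  expect_equal(out$values[3], 96)
  expect_true(is.na(out$values[5]))   # t = 2.0 maps to the missing input
})

test_that("empty channels resample to empty channels at the target rate", {
  ch <- ts_channel("WIRED_PPG", numeric(), rate = 75)
  out <- resample_channel(ch, 64)
  expect_equal(length(out$values), 0)
  expect_equal(out$rate, 64)
  expect_error(resample_channel(ch, -1), "positive")
})

test_that("a constructed offset between SpO2 streams is recovered exactly", {
  spec <- simulation_spec(duration_s = 1800, bt_dropout_rate_per_h = 0,
                          wireless_snr_db = 4, seed = 3)
  wired <- simulate_spo2_pair(spec, seed = 3)$wired
  for (k in c(-15, 0, 7, 40)) {
    shifted <- ts_channel("WIRELESS_SPO2", wired$values, rate = 1,
                          start_time = k)
    expect_equal(estimate_offset(wired, shifted, max_lag_s = 60), k)
  }
})

test_that("degenerate SpO2 traces yield instructive synchronization errors", {
  flat_a <- ts_channel("WIRED_SPO2", rep(95, 300), rate = 1)
  flat_b <- ts_channel("WIRELESS_SPO2", rep(95, 300), rate = 1)
  expect_error(estimate_offset(flat_a, flat_b), "offset explicitly")
  short_a <- ts_channel("WIRED_SPO2", 90 + sin(1:30), rate = 1)
  short_b <- ts_channel("WIRELESS_SPO2", 90 + sin(1:30), rate = 1)
  expect_error(estimate_offset(short_a, short_b), "insufficient|offset")
})

test_that("synchronize_recording aligns the wireless channels by the estimated offset", {
  rec <- make_tiny_recording(duration_s = 600, seed = 21)
  delayed <- rec
  # wireless SpO2 becomes a 5 s-delayed copy of the wired trace
  wired_vals <- rec$channels$WIRED_SPO2$values
  for (role in c("WIRELESS_PPG", "WIRELESS_SPO2")) {
    ch <- delayed$channels[[role]]
    if (role == "WIRELESS_SPO2") ch$values <- wired_vals
    drop_n <- round(5 * ch$rate)
    ch$values <- ch$values[seq_len(length(ch$values) - drop_n)]
    ch$start_time <- 5
    delayed$channels[[role]] <- ch
  }
  res <- suppressMessages(synchronize_recording(delayed, max_lag_s = 30))
  expect_equal(res$offset_s, 5)
  aligned <- res$recording$channels$WIRELESS_SPO2
  expect_equal(aligned$start_time, 0)
  expect_equal(aligned$values,
               wired_vals[seq_along(aligned$values)])
})
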