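test_that("the PPG generator closes the loop with the SNR estimator", {
  spec0 <- simulation_spec(duration_s = 600, wireless_snr_db = 0, seed = 42)
  snr0 <- estimate_snr(simulate_ppg(spec0, "WIRELESS_PPG", seed = 42))
  expect_lt(abs(median(snr0$snr_db, na.rm = TRUE) - 0), 1)

  spec7 <- simulation_spec(duration_s = 600, wired_snr_db = 7.35, seed = 42)
  snr7 <- estimate_snr(simulate_ppg(spec7, "WIRED_PPG", seed = 43))
  expect_lt(abs(median(snr7$snr_db, na.rm = TRUE) - 7.35), 1)
})

test_that("a noise-free PPG reports the capped maximum SNR", {
  spec <- simulation_spec(duration_s = 120, wired_snr_db = Inf)
  snr <- estimate_snr(simulate_ppg(spec, "WIRED_PPG", seed = 1))
  expect_true(all(snr$snr_db == 40, na.rm = TRUE))
})

test_that("generators are deterministic under a fixed seed", {
  spec <- simulation_spec(duration_s = 300, seed = 9)
  expect_identical(simulate_ppg(spec, "WIRELESS_PPG", seed = 9),
                   simulate_ppg(spec, "WIRELESS_PPG", seed = 9))
  expect_identical(simulate_day(spec), simulate_day(spec))
})

test_that("SpO2 pair honours bias, noise and desaturation contracts", {
  ident <- simulation_spec(duration_s = 300, device_bias_pct = 0,
                           device_noise_sd_pct = 0, desat_rate_per_h = 0,
                           seed = 5)
  pair <- simulate_spo2_pair(ident, seed = 5)
  expect_identical(pair$wired$values, pair$wireless$values)

  deep <- simulation_spec(duration_s = 1800, desat_rate_per_h = 4,
                          desat_depth_pct = 15, desat_duration_s = 60,
                          device_bias_pct = 0, device_noise_sd_pct = 0,
                          seed = 8)
  p2 <- simulate_spo2_pair(deep, seed = 8)
  expect_lte(min(p2$wired$values), deep$spo2_baseline_pct - 14)
  expect_true(all(p2$wired$values >= 0 & p2$wired$values <= 100))
})

test_that("inject_gaps applies listed removals, respects rate zero, and emits matching context", {
  spec0 <- simulation_spec(duration_s = 600, bt_dropout_rate_per_h = 0,
                           seed = 2)
  ch <- ts_channel("WIRELESS_SPO2", rep(95, 600), rate = 1)
  res0 <- inject_gaps(ch, spec0, seed = 2)
  expect_identical(res0$channel$values, ch$values)
  expect_equal(nrow(res0$gaps), 0)

  sr <- annotation_events(c("SR", "SA", "SR"),
                          c(100, 250, 400), c(130, 260, 430))
  spec_sr <- simulation_spec(duration_s = 600, bt_dropout_rate_per_h = 0,
                             sensor_removal_events = sr, seed = 2)
  res <- inject_gaps(ch, spec_sr, seed = 2)
  expect_equal(nrow(res$gaps), 3)
  expect_true(all(res$gaps$cause == "SR_SA"))
  expect_equal(res$annotations$start_s, sr$start_s)
  expect_equal(nrow(res$flags), 0)
})

test_that("detect_gaps recovers every injected Poisson gap boundary exactly", {
  spec <- simulation_spec(duration_s = 8 * 3600, bt_dropout_rate_per_h = 2,
                          wireless_snr_db = 4, seed = 77)
  ch <- ts_channel("WIRELESS_PPG",
                   rep(0, 64 * spec$duration_s), rate = 64)
  res <- inject_gaps(ch, spec, seed = 77)
  thr <- gap_thresholds()
  detected <- detect_gaps(res$channel, thr, spec$duration_s)
  expected <- detectable_gaps(res$gaps, thr)
  expect_gt(nrow(expected), 0)
  expect_equal(detected$start_s, expected$start_s)
  expect_equal(detected$end_s, expected$end_s)
})

test_that("simulate_day output satisfies all recording invariants and ground-truth bookkeeping", {
  spec <- simulation_spec(duration_s = 1200, seed = 31)
  sim <- simulate_day(spec)
  expect_silent(validate_recording(sim$recording))
  g <- sim$truth$injected_gaps
  expect_true(all(g$start_s >= 0 & g$end_s <= spec$duration_s))
  expect_true(all(g$cause %in% c("BD", "SR_SA", "LOW_SNR", "CABLE")))
  expect_true(all(sim$skin_scores$nscs %in% 3:9))
  expect_equal(sim$truth$true_bias_pct, spec$device_bias_pct)
})

test_that("the FiO2 profile drives the oxygen-group classification closed loop", {
  supp <- simulation_spec(duration_s = 1000,
                          fio2_profile = data.frame(start_s = c(0, 600),
                                                    fio2 = c(0.30, 0.21)),
                          seed = 4)
  sim <- simulate_day(supp)
  expect_equal(sim$truth$oxygen_group_truth, "SUPPLEMENTAL")
  expect_equal(classify_oxygen_group(sim$recording$channels$FIO2),
               "SUPPLEMENTAL")

  room <- simulation_spec(duration_s = 1000, seed = 4)
  sim2 <- simulate_day(room)
  expect_equal(classify_oxygen_group(sim2$recording$channels$FIO2),
               "ROOM_AIR")
})
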