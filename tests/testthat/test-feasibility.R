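test_that("gap detection uses strict threshold exceedance on the sample grid", {
  thr <- gap_thresholds()
  base <- rep(0, 64 * 10)

  v <- base; v[100:101] <- NA   # 2 samples = 31.25 ms: not strictly exceeding
  expect_equal(nrow(detect_gaps(ts_channel("WIRELESS_PPG", v, rate = 64),
                                thr, 10)), 0)

  v <- base; v[100:102] <- NA   # 3 samples = 46.875 ms
  g <- detect_gaps(ts_channel("WIRELESS_PPG", v, rate = 64), thr, 10)
  expect_equal(nrow(g), 1)
  expect_equal(g$duration_s, 3 / 64)
  expect_equal(g$start_s, 99 / 64)
  expect_equal(g$end_s, 102 / 64)
})

test_that("a 36 s SpO2 outage in an hour gives one gap and 99% coverage", {
  v <- rep(95, 3600)
  v[1001:1036] <- NA
  ch <- ts_channel("WIRED_SPO2", v, rate = 1)
  g <- detect_gaps(ch, gap_thresholds(), 3600)
  expect_equal(nrow(g), 1)
  expect_equal(g$duration_s, 36)
  cov <- coverage(ch, gap_thresholds(), 3600)
  expect_equal(cov$coverage_pct, 99.0)
})

test_that("coverage spans the full planned period, counting leading/trailing outages", {
  full <- ts_channel("WIRED_SPO2", rep(95, 3600), rate = 1)
  expect_equal(coverage(full, gap_thresholds(), 3600)$coverage_pct, 100)

  none <- ts_channel("WIRED_SPO2", rep(NA_real_, 3600), rate = 1)
  expect_equal(coverage(none, gap_thresholds(), 3600)$coverage_pct, 0)

  late <- ts_channel("WIRED_SPO2", rep(95, 3000), rate = 1, start_time = 300)
  cov <- coverage(late, gap_thresholds(), 3600)
  expect_equal(cov$n_gaps, 2)                       # leading and trailing
  expect_equal(cov$coverage_pct, 100 * 3000 / 3600)
})

test_that("coverage plus gap-time percentage is conserved on random missingness", {
  set.seed(1234)
  for (i in 1:20) {
    v <- rep(95, 1800)
    n_runs <- sample(0:6, 1)
    for (k in seq_len(n_runs)) {
      s <- sample(1700, 1)
      v[s:min(s + sample(1:120, 1), 1800)] <- NA
    }
    ch <- ts_channel("WIRED_SPO2", v, rate = 1)
    cov <- coverage(ch, gap_thresholds(), 1800)
    expect_lt(abs(cov$coverage_pct + 100 * cov$total_gap_time_s / 1800 - 100),
              1e-9)
  }
})

test_that("missing runs separated by a single valid sample stay distinct gaps", {
  v <- rep(95, 100)
  v[10:15] <- NA
  v[17:22] <- NA
  g <- detect_gaps(ts_channel("WIRED_SPO2", v, rate = 1),
                   gap_thresholds(), 100)
  expect_equal(nrow(g), 2)
})

test_that("SNR estimation caps pure tones, skips empty windows and is scale-invariant", {
  t <- (0:(64 * 90 - 1)) / 64
  tone <- sin(2 * pi * 2.5 * t)
  snr <- estimate_snr(ts_channel("WIRELESS_PPG", tone, rate = 64))
  expect_true(all(snr$snr_db == 40))

  gappy <- tone
  gappy[1:(64 * 30)] <- NA
  snr2 <- estimate_snr(ts_channel("WIRELESS_PPG", gappy, rate = 64))
  expect_true(is.na(snr2$snr_db[1]))

  set.seed(7)
  noisy <- tone + rnorm(length(tone))
  a <- estimate_snr(ts_channel("WIRELESS_PPG", noisy, rate = 64))
  b <- estimate_snr(ts_channel("WIRELESS_PPG", 250 * noisy, rate = 64))
  expect_equal(a$snr_db, b$snr_db, tolerance = 1e-9)
})

test_that("the attribution tree applies its rules in evidence order with activity context", {
  gaps <- data.frame(channel_id = "WIRELESS_SPO2",
                     start_s = c(100, 300, 500), end_s = c(120, 330, 520),
                     duration_s = c(20, 30, 20),
                     cause = NA_character_, activity = NA_character_)
  flags <- device_flags("BT_DISCONNECT", 95, 125)
  ann <- rbind(annotation_events("SA", 290, 335),
               annotation_events("KC", 450, 600))
  snr <- structure(
    data.frame(window_center_s = seq(15, 585, by = 15),
               snr_db = ifelse(seq(15, 585, by = 15) > 450, -5, 5)),
    class = c("snr_series", "data.frame"), window_s = 30)

  out <- attribute_gaps(gaps, flags, ann, snr)
  expect_equal(out$cause, c("BD", "SR_SA", "LOW_SNR"))
  expect_equal(out$activity, c("NONE", "NONE", "KC"))

  # rule precedence: a flagged gap inside an annotation is still BD
  out2 <- attribute_gaps(gaps[1, ], flags,
                         annotation_events("SR", 90, 130), snr)
  expect_equal(out2$cause, "BD")

  # wired fallback cause
  out3 <- attribute_gaps(gaps[2, ], device_flags(), annotation_events(),
                         snr, unknown_cause = "CABLE")
  expect_equal(out3$cause, "CABLE")
})

test_that("rank tests reproduce hand-computed statistics and degenerate cases", {
  u <- compare_unpaired(c(1, 2, 3), c(4, 5, 6))
  expect_equal(u$statistic, 6)
  expect_lt(u$z, 0)

  same <- compare_paired(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$n_nonzero, 0L)
  expect_match(same$note, "no usable pairs")

  expect_error(compare_paired(1:3, 1:4), "equal lengths")
  expect_error(compare_unpaired(1, c(2, 3)), "at least 2")
})
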