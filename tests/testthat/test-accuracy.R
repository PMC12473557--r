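test_that("pair_samples keeps exactly the jointly valid instants", {
  w <- ts_channel("WIRED_SPO2", rep(95, 100), rate = 1)
  l <- ts_channel("WIRELESS_SPO2", rep(94, 100), rate = 1)
  expect_equal(nrow(pair_samples(w, l)), 100)

  lv <- rep(94, 100); lv[1:30] <- NA
  expect_equal(nrow(pair_samples(w, ts_channel("WIRELESS_SPO2", lv,
                                               rate = 1))), 70)

  wv <- rep(95, 100); wv[1:50] <- NA
  lv2 <- rep(94, 100); lv2[51:100] <- NA
  disjoint <- pair_samples(ts_channel("WIRED_SPO2", wv, rate = 1),
                           ts_channel("WIRELESS_SPO2", lv2, rate = 1))
  expect_equal(nrow(disjoint), 0)

  off <- ts_channel("WIRELESS_SPO2", rep(94, 100), rate = 1,
                    start_time = 0.4)
  expect_error(pair_samples(w, off), "synchronize")
})

test_that("bland_altman matches the hand-computed example and identity case", {
  mk <- function(wired, wireless) {
    structure(data.frame(t_s = seq_along(wired) - 1, wired_pct = wired,
                         wireless_pct = wireless),
              class = c("paired_spo2", "data.frame"))
  }
  ident <- bland_altman(mk(rep(95, 10), rep(95, 10)))
  expect_equal(ident$bias, 0)
  expect_equal(c(ident$loa_low, ident$loa_high), c(0, 0))
  expect_equal(ident$mae, 0)

  # differences 1, 1, 1, 3
  s <- bland_altman(mk(c(95, 95, 95, 95), c(94, 94, 94, 92)))
  expect_equal(s$bias, 1.5)
  expect_equal(s$sd_d, 1.0)
  expect_equal(s$loa_low, 1.5 - 1.96)
  expect_equal(s$loa_high, 1.5 + 1.96)
  expect_equal(s$moe, 1.96)
  expect_equal(s$mae, 1.5)

  expect_error(bland_altman(mk(95, 94)), "at least 2")
})

test_that("agreement identities hold and direction swap negates the summary", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:200, 1)
    w <- runif(n, 85, 100)
    l <- pmin(pmax(w - rnorm(n, 1, 2), 0), 100)
    pairs <- structure(data.frame(t_s = seq_len(n) - 1, wired_pct = w,
                                  wireless_pct = l),
                       class = c("paired_spo2", "data.frame"))
    s <- bland_altman(pairs)
    expect_equal(s$loa_high - s$loa_low, 2 * s$moe, tolerance = 1e-12)
    expect_gte(s$mae, abs(s$bias) - 1e-12)
    r <- bland_altman(pairs, direction = "wireless_minus_wired")
    expect_equal(r$bias, -s$bias)
    expect_equal(r$loa_low, -s$loa_high)
    expect_equal(r$loa_high, -s$loa_low)
    expect_equal(r$mae, s$mae)
  }
})

test_that("aggregate_daily reports linear-interpolation medians and IQRs per metric", {
  one <- bland_altman(structure(
    data.frame(t_s = 0:3, wired_pct = c(95, 95, 95, 95),
               wireless_pct = c(94, 94, 94, 92)),
    class = c("paired_spo2", "data.frame")))
  agg1 <- aggregate_daily(list(one))
  expect_equal(agg1$median[agg1$metric == "bias"], 1.5)
  expect_equal(agg1$q1, agg1$q3)

  three <- do.call(rbind, lapply(c(0, 1, 2), function(b) {
    s <- one; s$bias <- 1 + b; s
  }))
  agg3 <- aggregate_daily(three)
  expect_equal(agg3$median[agg3$metric == "bias"], 2)
  expect_error(aggregate_daily(list()), "no agreement")
})

test_that("oxygen grouping uses a strict majority of valid FiO2 samples", {
  expect_equal(classify_oxygen_group(
    ts_channel("FIO2", rep(0.21, 100), rate = 1)), "ROOM_AIR")
  expect_equal(classify_oxygen_group(
    ts_channel("FIO2", c(rep(0.30, 60), rep(0.21, 40)), rate = 1)),
    "SUPPLEMENTAL")
  expect_equal(classify_oxygen_group(
    ts_channel("FIO2", c(rep(0.30, 50), rep(0.21, 50)), rate = 1)),
    "ROOM_AIR")   # exactly 50% is not a majority
  expect_error(classify_oxygen_group(
    ts_channel("FIO2", rep(NA_real_, 10), rate = 1)), "no valid")
})

test_that("error-grid worked examples classify as expected", {
  expect_equal(ega_classify(90, 89, "ROOM_AIR"), "A")
  expect_equal(ega_classify(97, 92, "SUPPLEMENTAL"), "D")
  expect_equal(ega_classify(98, 85, "SUPPLEMENTAL"), "E")
  expect_equal(ega_classify(99, 92, "ROOM_AIR"), "B")   # same state, far
  expect_equal(ega_classify(93, 87, "SUPPLEMENTAL"), "C")
  expect_error(ega_classify(101, 95, "ROOM_AIR"), "\\[0, 100\\]")
})

test_that("the grid classifier agrees with the brute-force oracle on all integer pairs", {
  grid <- expand.grid(ref = 50:100, test = 50:100)
  for (group in c("ROOM_AIR", "SUPPLEMENTAL")) {
    got <- ega_classify(grid$ref, grid$test, group)
    want <- mapply(ega_oracle_one, grid$ref, grid$test,
                   MoreArgs = list(group = group))
    expect_identical(got, unname(want))
    if (group == "ROOM_AIR") expect_false(any(got == "E"))
  }
})

test_that("ega_summary counts regions with the wired device as reference", {
  mk <- function(w, l) structure(
    data.frame(t_s = seq_along(w) - 1, wired_pct = w, wireless_pct = l),
    class = c("paired_spo2", "data.frame"))
  all_a <- ega_summary(mk(rep(95, 20), rep(95, 20)), "ROOM_AIR")
  expect_equal(unname(as.numeric(all_a$proportions["A"])), 1)

  all_d <- ega_summary(mk(rep(97, 10), rep(92, 10)), "SUPPLEMENTAL")
  expect_equal(unname(as.numeric(all_d$proportions["D"])), 1)

  w <- c(90, 95, 98, 85, 97, 92, 96, 99, 88, 93)
  l <- c(89, 94, 90, 96, 92, 91, 85, 98, 94, 87)
  s <- ega_summary(mk(w, l), "SUPPLEMENTAL")
  want <- table(factor(mapply(ega_oracle_one, w, l,
                              MoreArgs = list(group = "SUPPLEMENTAL")),
                       levels = c("A", "B", "C", "D", "E")))
  expect_equal(as.numeric(s$counts), as.numeric(want))
  expect_equal(sum(s$proportions), 1, tolerance = 1e-9)
  expect_error(ega_summary(mk(numeric(), numeric()), "ROOM_AIR"), "no pairs")
})

test_that("SNR-stratified error map reduces to global MAE with one bin and bins left-closed", {
  spec <- simulation_spec(duration_s = 1200, bt_dropout_rate_per_h = 0,
                          wireless_snr_db = 4, seed = 17)
  sim <- simulate_day(spec)
  rec <- sim$recording
  pairs <- pair_samples(rec$channels$WIRED_SPO2, rec$channels$WIRELESS_SPO2)
  snr_w <- estimate_snr(rec$channels$WIRED_PPG)
  snr_l <- estimate_snr(rec$channels$WIRELESS_PPG)

  one <- error_by_snr(pairs, snr_w, snr_l, bin_edges_db = c(-40, 40))
  expect_equal(nrow(one), 1)
  expect_equal(one$mae, bland_altman(pairs)$mae, tolerance = 1e-12)
  expect_equal(one$n, nrow(pairs))
  expect_identical(one$low_n, one$n < 30)

  # a value exactly on an edge lands in the bin to its right
  fake_snr <- function(db) structure(
    data.frame(window_center_s = c(0, 1e9), snr_db = c(db, db)),
    class = c("snr_series", "data.frame"), window_s = 30)
  cell <- error_by_snr(pairs[1:5, ], fake_snr(0), fake_snr(0),
                       bin_edges_db = c(-10, 0, 10))
  expect_equal(cell$wired_bin, "[0,10)")
  expect_equal(cell$wireless_bin, "[0,10)")
})

test_that("the experimental minimally detectable difference scales as sd/sqrt(n)", {
  expect_equal(mdd(2, 100), (qnorm(0.975) + qnorm(0.9)) * 2 / 10)
  expect_equal(mdd(2, 400), mdd(2, 100) / 2)
})
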