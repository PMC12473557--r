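# Accuracy analysis: sample-to-sample SpO2 agreement (Bland-Altman, MAE,
# MoE), per-day aggregation, oxygen-group classification, the modified
# Clarke error grid under neonatal alarm thresholds, and SNR-stratified
# error maps.

#' Neonatal SpO2 alarm thresholds and the error-grid agreement band
#'
#' Alarm targets: SpO2 above 91% for infants breathing room air (alarm state
#' at values at or below 91), and between above-88% and at-most-95% for
#' infants on supplemental oxygen. `within_band` is the absolute agreement
#' band of error-grid region A, in percentage points (inclusive).
#'
#' @param room_air_low,supp_low,supp_high Threshold values, percent.
#' @param within_band Region-A band, percentage points.
#' @return A list of class `oxygen_targets`.
#' @export
oxygen_targets <- function(room_air_low = 91, supp_low = 88, supp_high = 95,
                           within_band = 5) {
  if (supp_low >= supp_high) stop("supp_low must be < supp_high", call. = FALSE)
  if (within_band <= 0) stop("within_band must be positive", call. = FALSE)
  structure(list(room_air_low = room_air_low, supp_low = supp_low,
                 supp_high = supp_high, within_band = within_band),
            class = "oxygen_targets")
}

#' Pair wired and wireless SpO2 samples
#'
#' Retains exactly the instants where both 1 Hz channels carry a valid value.
#' Both channels must already be on the common synchronized grid (same rate;
#' start times differing by an integer number of samples).
#'
#' @param wired_spo2,wireless_spo2 1 Hz `ts_channel`s.
#' @return A data.frame of class `paired_spo2` with columns t_s, wired_pct,
#'   wireless_pct.
#' @export
pair_samples <- function(wired_spo2, wireless_spo2) {
  stopifnot(inherits(wired_spo2, "ts_channel"),
            inherits(wireless_spo2, "ts_channel"))
  if (wired_spo2$rate != wireless_spo2$rate)
    stop("channels are on different rates; synchronize/resample first",
         call. = FALSE)
  r <- wired_spo2$rate
  shift <- (wireless_spo2$start_time - wired_spo2$start_time) * r
  if (abs(shift - round(shift)) > 1e-9)
    stop("channel grids are misaligned; synchronize first", call. = FALSE)
  shift <- round(shift)
  i <- seq_along(wired_spo2$values)
  j <- i - shift
  ok <- j >= 1 & j <= length(wireless_spo2$values)
  i <- i[ok]; j <- j[ok]
  both <- !is.na(wired_spo2$values[i]) & !is.na(wireless_spo2$values[j])
  structure(data.frame(
    t_s = wired_spo2$start_time + (i[both] - 1) / r,
    wired_pct = wired_spo2$values[i[both]],
    wireless_pct = wireless_spo2$values[j[both]]),
    class = c("paired_spo2", "data.frame"))
}

#' Bland-Altman agreement summary
#'
#' Computes per-pair differences (wired minus wireless by default, so that a
#' positive bias means the wireless device reads lower), the mean bias, the
#' sample SD of the differences, the 95% limits of agreement
#' bias +/- 1.96 SD, the margin of error MoE = 1.96 SD, and the mean
#' absolute error.
#'
#' @param pairs A `paired_spo2` from [pair_samples()].
#' @param direction `"wired_minus_wireless"` or `"wireless_minus_wired"`.
#' @return A one-row data.frame of class `agreement_summary`: n_pairs, bias,
#'   sd_d, loa_low, loa_high, moe, mae.
#' @export
bland_altman <- function(pairs, direction = c("wired_minus_wireless",
                                              "wireless_minus_wired")) {
  direction <- match.arg(direction)
  if (nrow(pairs) < 2)
    stop("Bland-Altman analysis needs at least 2 pairs", call. = FALSE)
  d <- pairs$wired_pct - pairs$wireless_pct
  if (direction == "wireless_minus_wired") d <- -d
  bias <- mean(d)
  sd_d <- stats::sd(d)
  structure(data.frame(n_pairs = nrow(pairs), bias = bias, sd_d = sd_d,
                       loa_low = bias - 1.96 * sd_d,
                       loa_high = bias + 1.96 * sd_d,
                       moe = 1.96 * sd_d, mae = mean(abs(d))),
            class = c("agreement_summary", "data.frame"))
}

#' Aggregate per-day agreement summaries
#'
#' Medians and interquartile ranges across recording days for each agreement
#' metric, using linear-interpolation quantiles.
#'
#' @param summaries A list of `agreement_summary` rows (or a data.frame of
#'   them row-bound).
#' @return A data.frame with one row per metric: metric, median, q1, q3.
#' @export
aggregate_daily <- function(summaries) {
  if (is.data.frame(summaries)) df <- summaries
  else df <- do.call(rbind, summaries)
  if (is.null(df) || !nrow(df))
    stop("no agreement summaries to aggregate", call. = FALSE)
  metrics <- c("bias", "moe", "loa_low", "loa_high", "mae")
  out <- do.call(rbind, lapply(metrics, function(m) {
    q <- stats::quantile(df[[m]], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(metric = m, median = q[2], q1 = q[1], q3 = q[3])
  }))
  rownames(out) <- NULL
  out
}

#' Classify a recording day's oxygen group from its FiO2 trace
#'
#' A day counts as supplemental oxygen when FiO2 exceeded 0.21 for strictly
#' more than 50% of the monitoring period, the fraction being computed over
#' valid FiO2 samples.
#'
#' @param fio2 The FiO2 `ts_channel`.
#' @return `"ROOM_AIR"` or `"SUPPLEMENTAL"`.
#' @export
classify_oxygen_group <- function(fio2) {
  stopifnot(inherits(fio2, "ts_channel"))
  v <- fio2$values[!is.na(fio2$values)]
  if (!length(v)) stop("no valid FiO2 samples", call. = FALSE)
  if (mean(v > 0.21) > 0.5) "SUPPLEMENTAL" else "ROOM_AIR"
}

# Clinical state of an SpO2 value under the group's alarm thresholds.
# ROOM_AIR has two states (LOW at <= 91, else NORMAL); SUPPLEMENTAL has
# three (LOW at <= 88, HIGH above 95, else IN_RANGE).
spo2_state <- function(value, group, targets) {
  if (group == "ROOM_AIR") {
    ifelse(value <= targets$room_air_low, "LOW", "NORMAL")
  } else {
    ifelse(value <= targets$supp_low, "LOW",
           ifelse(value > targets$supp_high, "HIGH", "IN_RANGE"))
  }
}

#' Classify paired SpO2 values on the modified Clarke error grid
#'
#' Each (reference, test) pair is assigned a region from the clinical states
#' of the two values under the group's alarm thresholds:
#' \itemize{
#'   \item A -- same state and absolute difference within the agreement band;
#'   \item B -- same state but difference beyond the band;
#'   \item C -- reference in an acceptable state, test in an alarm state
#'     (false alarm / over-treatment);
#'   \item D -- reference in an alarm state, test acceptable
#'     (failure to treat);
#'   \item E -- opposite alarm states (reference LOW, test HIGH or vice
#'     versa; reverse treatment). Unreachable in ROOM_AIR, which has only
#'     two states.
#' }
#' State agreement takes precedence over the numeric band: pairs in different
#' states are C/D/E however close the values are.
#'
#' @param ref_pct Reference (wired) SpO2 values, percent.
#' @param test_pct Test (wireless) SpO2 values, percent.
#' @param group `"ROOM_AIR"` or `"SUPPLEMENTAL"`.
#' @param targets An [oxygen_targets()].
#' @return Character vector of regions `"A"`-`"E"`.
#' @export
ega_classify <- function(ref_pct, test_pct,
                         group = c("ROOM_AIR", "SUPPLEMENTAL"),
                         targets = oxygen_targets()) {
  group <- match.arg(group)
  if (length(ref_pct) != length(test_pct))
    stop("ref and test must have equal length", call. = FALSE)
  if (any(ref_pct < 0 | ref_pct > 100 | test_pct < 0 | test_pct > 100,
          na.rm = TRUE))
    stop("SpO2 values must lie in [0, 100]", call. = FALSE)
  rs <- spo2_state(ref_pct, group, targets)
  ts <- spo2_state(test_pct, group, targets)
  alarm <- c("LOW", "HIGH")
  region <- character(length(ref_pct))
  same <- rs == ts
  within <- abs(test_pct - ref_pct) <= targets$within_band
  region[same & within] <- "A"
  region[same & !within] <- "B"
  opposite <- (rs == "LOW" & ts == "HIGH") | (rs == "HIGH" & ts == "LOW")
  region[!same & opposite] <- "E"
  region[!same & !opposite & rs %in% alarm] <- "D"
  region[!same & !opposite & !(rs %in% alarm)] <- "C"
  region
}

#' Summarize error-grid regions for a paired series
#'
#' Classifies every pair with the wired device as reference and reports
#' counts and proportions per region.
#'
#' @param pairs A `paired_spo2`.
#' @inheritParams ega_classify
#' @return A list of class `ega_summary`: group, n_pairs, counts (named A-E),
#'   proportions.
#' @export
ega_summary <- function(pairs, group = c("ROOM_AIR", "SUPPLEMENTAL"),
                        targets = oxygen_targets()) {
  group <- match.arg(group)
  if (!nrow(pairs)) stop("no pairs to classify", call. = FALSE)
  region <- ega_classify(pairs$wired_pct, pairs$wireless_pct, group, targets)
  counts <- table(factor(region, levels = c("A", "B", "C", "D", "E")))
  structure(list(group = group, n_pairs = nrow(pairs),
                 counts = counts, proportions = counts / nrow(pairs)),
            class = "ega_summary")
}

#' @export
print.ega_summary <- function(x, ...) {
  cat(sprintf("<ega_summary> %s, %d pairs\n", x$group, x$n_pairs))
  print(round(100 * x$proportions, 1))
  invisible(x)
}

#' SNR-stratified error map
#'
#' Assigns every SpO2 pair to the nearest SNR window of each device's PPG and
#' bins the two SNR values with left-closed, right-open bins; per cell it
#' reports MAE, MoE and the pair count, flagging cells with fewer than
#' `low_n` pairs. Pairs whose nearest window has a missing SNR are dropped.
#'
#' @param pairs A `paired_spo2`.
#' @param snr_wired,snr_wireless `snr_series` for the two PPG channels.
#' @param bin_edges_db Numeric vector of bin edges, dB.
#' @param low_n Minimum pairs per cell before the low-n flag.
#' @return A data.frame with one row per non-empty cell: wired_bin,
#'   wireless_bin (labels), mae, moe, n, low_n.
#' @export
error_by_snr <- function(pairs, snr_wired, snr_wireless,
                         bin_edges_db = seq(-40, 40, by = 10), low_n = 30) {
  if (!nrow(pairs)) stop("no pairs", call. = FALSE)
  nearest_snr <- function(snr, t) {
    idx <- vapply(t, function(tt)
      which.min(abs(snr$window_center_s - tt)), integer(1))
    snr$snr_db[idx]
  }
  sw <- nearest_snr(snr_wired, pairs$t_s)
  sl <- nearest_snr(snr_wireless, pairs$t_s)
  d <- pairs$wired_pct - pairs$wireless_pct
  keep <- !is.na(sw) & !is.na(sl)
  bw <- findInterval(sw[keep], bin_edges_db, left.open = FALSE)
  bl <- findInterval(sl[keep], bin_edges_db, left.open = FALSE)
  labels <- function(i) {
    lab <- character(length(i))
    inside <- i >= 1 & i < length(bin_edges_db)
    lab[inside] <- sprintf("[%g,%g)", bin_edges_db[i[inside]],
                           bin_edges_db[i[inside] + 1])
    lab[!inside] <- ifelse(i[!inside] < 1, "below", "above")
    lab
  }
  df <- data.frame(wired_bin = labels(bw), wireless_bin = labels(bl),
                   d = d[keep])
  out <- do.call(rbind, lapply(
    split(df, list(df$wired_bin, df$wireless_bin), drop = TRUE),
    function(cell) data.frame(
      wired_bin = cell$wired_bin[1], wireless_bin = cell$wireless_bin[1],
      mae = mean(abs(cell$d)),
      moe = if (nrow(cell) >= 2) 1.96 * stats::sd(cell$d) else NA_real_,
      n = nrow(cell))))
  rownames(out) <- NULL
  out$low_n <- out$n < low_n
  out
}

#' Minimally detectable difference (experimental)
#'
#' An experimental helper returning the shift detectable from `n` paired
#' differences with SD `sd_d` at two-sided alpha 0.05 and 90% power,
#' `(z[0.975] + z[0.90]) * sd_d / sqrt(n)`. The definition of the published
#' per-metric "effect size" this mirrors is not standardized; treat the value
#' as unverified and do not report it by default.
#'
#' @param sd_d SD of paired differences.
#' @param n Number of pairs.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return The minimally detectable difference, same units as `sd_d`.
#' @export
mdd <- function(sd_d, n, alpha = 0.05, power = 0.90) {
  (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) * sd_d / sqrt(n)
}
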