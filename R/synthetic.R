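# Synthetic dual-device day generator with ground truth.
#
# Emulates the statistical structure the analysis assumes: pulsatile PPG at
# the device rates with scheduled band-power SNR, a mean-reverting SpO2
# baseline with desaturation excursions, a wireless stream offset by a
# device bias plus sample noise, Bluetooth-dropout and sensor-removal gap
# processes with matching device flags / annotations, low-SNR-driven
# wireless SpO2 missingness, an FiO2 profile, and before/after skin scores.
# Every stochastic draw flows from one seed per simulated day.

normalize_schedule <- function(x, value_col) {
  if (is.data.frame(x)) {
    stopifnot(all(c("start_s", value_col) %in% names(x)))
    x[order(x$start_s), , drop = FALSE]
  } else {
    out <- data.frame(start_s = 0)
    out[[value_col]] <- as.numeric(x)
    out
  }
}

# Default wireless SNR schedule: repeating 20 min blocks whose final 30% sit
# below 0 dB, emulating a wireless stream whose SpO2 availability is
# dominated by low-signal-quality episodes (roughly a third of the day).
default_wireless_snr_schedule <- function(duration_s,
                                          good_db = 4, bad_db = -4,
                                          block_s = 1200, bad_frac = 0.3) {
  starts <- seq(0, duration_s - 1e-9, by = block_s)
  df <- do.call(rbind, lapply(starts, function(s)
    data.frame(start_s = c(s, s + block_s * (1 - bad_frac)),
               snr_db = c(good_db, bad_db))))
  df[df$start_s < duration_s, , drop = FALSE]
}

#' Build a simulation specification
#'
#' Parameters of one synthetic infant-day. Defaults describe an 8 h neonatal
#' recording: heart rate 150 bpm; wired PPG SNR constant at 7.35 dB and a
#' wireless schedule alternating +4 / -4 dB with 30% of time below 0 dB;
#' SpO2 baseline 97% with 2 desaturations/h of depth 10 points over 60 s;
#' wireless device bias 1.34 points (wired minus wireless) with sample noise
#' SD 2.0 points; Bluetooth dropouts at 2/h with mean 30 s; wired cable
#' dropouts at 0.07/h with mean 30 s; room-air FiO2.
#'
#' @param duration_s Recording length, seconds.
#' @param heart_rate_bpm Pulse rate of the synthetic PPG, beats/min.
#' @param wired_snr_db,wireless_snr_db Piecewise-constant SNR schedules:
#'   either a scalar (dB) or a data.frame(start_s, snr_db).
#' @param spo2_baseline_pct Mean SpO2 of the baseline process, percent.
#' @param desat_rate_per_h,desat_depth_pct,desat_duration_s Desaturation
#'   event process: Poisson rate, excursion depth (points) and duration (s).
#' @param device_bias_pct Systematic wired-minus-wireless SpO2 offset.
#' @param device_noise_sd_pct SD of the wireless SpO2 sample noise, points.
#' @param bt_dropout_rate_per_h,bt_dropout_mean_s Bluetooth-dropout Poisson
#'   rate and exponential mean duration.
#' @param cable_dropout_rate_per_h,cable_dropout_mean_s Wired-cable dropout
#'   process.
#' @param sensor_removal_events Annotation table of planned SR/SA intervals.
#' @param care_activities Annotation table of care activities (KC/RC/PAU/O).
#' @param fio2_profile Piecewise-constant FiO2: data.frame(start_s, fio2).
#' @param ou_tau_s,ou_sigma Relaxation time (s) and per-step innovation SD of
#'   the mean-reverting SpO2 baseline.
#' @param seed Integer seed for [simulate_day()].
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(duration_s = 8 * 3600,
                            heart_rate_bpm = 150,
                            wired_snr_db = 7.35,
                            wireless_snr_db = NULL,
                            spo2_baseline_pct = 97,
                            desat_rate_per_h = 2,
                            desat_depth_pct = 10,
                            desat_duration_s = 60,
                            device_bias_pct = 1.34,
                            device_noise_sd_pct = 2.0,
                            bt_dropout_rate_per_h = 2,
                            bt_dropout_mean_s = 30,
                            cable_dropout_rate_per_h = 0.07,
                            cable_dropout_mean_s = 30,
                            sensor_removal_events = annotation_events(),
                            care_activities = annotation_events(),
                            fio2_profile = data.frame(start_s = 0,
                                                      fio2 = 0.21),
                            ou_tau_s = 300, ou_sigma = 0.05,
                            seed = 1L) {
  if (is.null(wireless_snr_db))
    wireless_snr_db <- default_wireless_snr_schedule(duration_s)
  spec <- list(
    duration_s = duration_s, heart_rate_bpm = heart_rate_bpm,
    wired_snr_db = normalize_schedule(wired_snr_db, "snr_db"),
    wireless_snr_db = normalize_schedule(wireless_snr_db, "snr_db"),
    spo2_baseline_pct = spo2_baseline_pct,
    desat_rate_per_h = desat_rate_per_h,
    desat_depth_pct = desat_depth_pct,
    desat_duration_s = desat_duration_s,
    device_bias_pct = device_bias_pct,
    device_noise_sd_pct = device_noise_sd_pct,
    bt_dropout_rate_per_h = bt_dropout_rate_per_h,
    bt_dropout_mean_s = bt_dropout_mean_s,
    cable_dropout_rate_per_h = cable_dropout_rate_per_h,
    cable_dropout_mean_s = cable_dropout_mean_s,
    sensor_removal_events = sensor_removal_events,
    care_activities = care_activities,
    fio2_profile = normalize_schedule(fio2_profile, "fio2"),
    ou_tau_s = ou_tau_s, ou_sigma = ou_sigma, seed = as.integer(seed))
  rates <- c(spec$duration_s, spec$heart_rate_bpm, spec$desat_rate_per_h,
             spec$desat_duration_s, spec$device_noise_sd_pct,
             spec$bt_dropout_rate_per_h, spec$bt_dropout_mean_s,
             spec$cable_dropout_rate_per_h, spec$cable_dropout_mean_s,
             spec$ou_tau_s, spec$ou_sigma)
  if (any(!is.finite(rates)) || any(rates < 0) || spec$duration_s <= 0)
    stop("simulation rates/durations must be non-negative and finite",
         call. = FALSE)
  if (any(spec$fio2_profile$fio2 < 0.21 | spec$fio2_profile$fio2 > 1))
    stop("fio2_profile values must lie in [0.21, 1.0]", call. = FALSE)
  structure(spec, class = "simulation_spec")
}

schedule_at <- function(schedule, t, value_col) {
  idx <- findInterval(t, schedule$start_s)
  idx[idx < 1] <- 1L
  schedule[[value_col]][idx]
}

# Convert a piecewise schedule into intervals [start, end) over the day.
schedule_intervals <- function(schedule, duration_s, value_col) {
  ends <- c(schedule$start_s[-1], duration_s)
  data.frame(start_s = schedule$start_s, end_s = ends,
             value = schedule[[value_col]])
}

#' Simulate a PPG channel with scheduled SNR
#'
#' The waveform is a periodic pulse at the spec's heart rate (fundamental
#' plus one harmonic at half amplitude) in white Gaussian noise whose
#' variance is set, segment by segment, so that the band-power SNR seen by
#' [estimate_snr()] -- cardiac-band signal power against residual 0.1-10 Hz
#' noise power -- matches the scheduled value. Sampled at 75 Hz for the wired
#' role and 64 Hz for the wireless role. An infinite scheduled SNR yields a
#' noise-free waveform.
#'
#' @param spec A `simulation_spec`.
#' @param channel_role `"WIRED_PPG"` or `"WIRELESS_PPG"`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A `ts_channel`.
#' @export
simulate_ppg <- function(spec, channel_role = c("WIRED_PPG", "WIRELESS_PPG"),
                         seed = NULL) {
  channel_role <- match.arg(channel_role)
  if (!is.null(seed)) set.seed(seed)
  fs <- unname(channel_roles()[channel_role])
  n <- round(spec$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  f0 <- spec$heart_rate_bpm / 60
  pulse <- sin(2 * pi * f0 * t) + 0.5 * sin(4 * pi * f0 * t)
  p_sig <- (1 + 0.5^2) / 2
  schedule <- if (channel_role == "WIRED_PPG") spec$wired_snr_db
    else spec$wireless_snr_db
  snr_t <- schedule_at(schedule, t, "snr_db")
  # white noise spreads evenly over [0, fs/2]; scale its variance so the
  # portion landing in the estimator's noise band matches the target ratio
  band_w <- function(center) {
    max(min(center + 0.3, 10) - max(center - 0.3, 0.1), 0)
  }
  b_sig <- band_w(f0) + band_w(2 * f0)
  b_noise <- (10 - 0.1) - b_sig
  sigma <- sqrt(p_sig / 10^(snr_t / 10) * (fs / 2) / b_noise)
  sigma[!is.finite(sigma)] <- 0
  values <- pulse + stats::rnorm(n) * sigma
  ts_channel(channel_role, values, rate = fs, start_time = 0)
}

#' Simulate a paired wired/wireless SpO2 day
#'
#' The wired trace is a mean-reverting (Ornstein-Uhlenbeck-style) baseline
#' around `spo2_baseline_pct` with raised-cosine desaturation excursions,
#' sampled at 1 Hz and clipped to `[0, 100]`. The wireless trace is the wired
#' trace minus `device_bias_pct` plus Gaussian sample noise
#' (`device_noise_sd_pct`), clipped to `[0, 100]`. Missingness is injected
#' separately (see [inject_gaps()]).
#'
#' @param spec A `simulation_spec`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A list with `wired` and `wireless` `ts_channel`s.
#' @export
simulate_spo2_pair <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(spec$duration_s)
  mu <- spec$spo2_baseline_pct
  x <- numeric(n)
  x[1] <- mu
  innov <- stats::rnorm(n) * spec$ou_sigma
  for (i in seq_len(n - 1)) {
    x[i + 1] <- x[i] + (mu - x[i]) / spec$ou_tau_s + innov[i]
  }
  n_desat <- stats::rpois(1, spec$desat_rate_per_h * spec$duration_s / 3600)
  if (n_desat > 0) {
    starts <- sort(stats::runif(n_desat, 0,
                                spec$duration_s - spec$desat_duration_s))
    t <- seq_len(n) - 1
    for (s in starts) {
      inside <- t >= s & t < s + spec$desat_duration_s
      phase <- (t[inside] - s) / spec$desat_duration_s
      x[inside] <- x[inside] -
        spec$desat_depth_pct * 0.5 * (1 - cos(2 * pi * phase))
    }
  }
  wired <- pmin(pmax(x, 0), 100)
  wireless <- pmin(pmax(
    wired - spec$device_bias_pct +
      stats::rnorm(n) * spec$device_noise_sd_pct, 0), 100)
  list(wired = ts_channel("WIRED_SPO2", wired, rate = 1, start_time = 0),
       wireless = ts_channel("WIRELESS_SPO2", wireless, rate = 1,
                             start_time = 0))
}

# Poisson interval process: event count ~ Poisson(rate * horizon), uniform
# starts, exponential durations, clipped to the horizon.
sample_poisson_intervals <- function(rate_per_h, mean_s, duration_s) {
  k <- stats::rpois(1, rate_per_h * duration_s / 3600)
  if (k == 0)
    return(data.frame(start_s = numeric(), end_s = numeric()))
  start <- sort(stats::runif(k, 0, duration_s))
  dur <- stats::rexp(k, 1 / mean_s)
  data.frame(start_s = start, end_s = pmin(start + dur, duration_s))
}

# Drop intervals whose padded extent comes within `sep_s` of any protected
# interval, so that injected causes stay identifiable by the attribution
# tree's padded overlap rules.
drop_near <- function(intervals, protected, sep_s) {
  if (!nrow(intervals) || is.null(protected) || !nrow(protected))
    return(intervals)
  keep <- vapply(seq_len(nrow(intervals)), function(i) {
    !any(interval_overlaps(intervals$start_s[i] - sep_s,
                           intervals$end_s[i] + sep_s,
                           protected$start_s, protected$end_s))
  }, logical(1))
  intervals[keep, , drop = FALSE]
}

# Snap an interval [start_s, end_s) to a channel's sample grid: the set of
# samples whose half-open supports intersect the interval.
snap_interval <- function(start_s, end_s, rate, n) {
  i1 <- max(floor(start_s * rate + 1e-9) + 1, 1)
  i2 <- min(ceiling(end_s * rate - 1e-9), n)
  if (i2 < i1) return(NULL)
  c(i1, i2)
}

cause_rank <- function(cause) {
  match(cause, c("BD", "SR_SA", "LOW_SNR", "CABLE", "UNKNOWN"))
}

# Blank the samples covered by each interval and return the merged missing
# runs as ground-truth gaps (grid-snapped, half-open), with overlapping or
# sample-adjacent injections merged under cause precedence
# BD > SR_SA > LOW_SNR > CABLE > UNKNOWN.
inject_intervals <- function(channel, intervals, causes) {
  n <- length(channel$values)
  r <- channel$rate
  snapped <- list()
  for (k in seq_len(nrow(intervals))) {
    s <- snap_interval(intervals$start_s[k] - channel$start_time,
                       intervals$end_s[k] - channel$start_time, r, n)
    if (!is.null(s))
      snapped[[length(snapped) + 1]] <- data.frame(i1 = s[1], i2 = s[2],
                                                   cause = causes[k])
  }
  empty <- data.frame(channel_id = character(), start_s = numeric(),
                      end_s = numeric(), duration_s = numeric(),
                      cause = character())
  if (!length(snapped)) return(list(channel = channel, gaps = empty))
  df <- do.call(rbind, snapped)
  df <- df[order(df$i1, df$i2), , drop = FALSE]
  merged <- df[1, , drop = FALSE]
  for (k in seq_len(nrow(df))[-1]) {
    last <- nrow(merged)
    if (df$i1[k] <= merged$i2[last] + 1) {   # overlap or sample-adjacent
      merged$i2[last] <- max(merged$i2[last], df$i2[k])
      if (cause_rank(df$cause[k]) < cause_rank(merged$cause[last]))
        merged$cause[last] <- df$cause[k]
    } else {
      merged <- rbind(merged, df[k, , drop = FALSE])
    }
  }
  for (k in seq_len(nrow(merged)))
    channel$values[merged$i1[k]:merged$i2[k]] <- NA
  gaps <- data.frame(channel_id = channel$channel_id,
                     start_s = channel$start_time + (merged$i1 - 1) / r,
                     end_s = channel$start_time + merged$i2 / r,
                     duration_s = (merged$i2 - merged$i1 + 1) / r,
                     cause = merged$cause)
  list(channel = channel, gaps = gaps)
}

#' Inject gap processes into a channel
#'
#' Draws Bluetooth-dropout gaps from a Poisson process with exponential
#' durations and applies the spec's listed sensor-removal intervals; blanks
#' the covered samples; and emits the matching `BT_DISCONNECT` flags and
#' SR/SA annotations so the attribution tree can recover each cause.
#' Overlapping or sample-adjacent injections are merged with cause precedence
#' BD > SR_SA. Bluetooth draws landing within `2 * context_pad_s` of a listed
#' sensor-removal interval are discarded so that the padded overlap rules
#' cannot confuse the two mechanisms.
#'
#' @param channel A `ts_channel`.
#' @param spec A `simulation_spec`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @param context_pad_s The attribution padding the injections must respect.
#' @return A list with `channel` (samples blanked), `gaps` (ground-truth gap
#'   table with causes), `flags` and `annotations`.
#' @export
inject_gaps <- function(channel, spec, seed = NULL, context_pad_s = 5) {
  if (!is.null(seed)) set.seed(seed)
  bt <- sample_poisson_intervals(spec$bt_dropout_rate_per_h,
                                 spec$bt_dropout_mean_s, spec$duration_s)
  sr <- spec$sensor_removal_events
  bt <- drop_near(bt, sr, 2 * context_pad_s)
  intervals <- rbind(bt[, c("start_s", "end_s"), drop = FALSE],
                     sr[, c("start_s", "end_s"), drop = FALSE])
  causes <- c(rep("BD", nrow(bt)), rep("SR_SA", nrow(sr)))
  res <- inject_intervals(channel, intervals, causes)
  res$flags <- device_flags(rep("BT_DISCONNECT", nrow(bt)),
                            bt$start_s, bt$end_s)
  res$annotations <- annotation_events(sr$label, sr$start_s, sr$end_s)
  res
}

#' Simulate one dual-device infant-day with ground truth
#'
#' Composes the channel simulators and gap processes into a validated
#' [dual_day_recording()] plus the ground truth needed for closed-loop
#' parameter-recovery tests. Bluetooth events are drawn once and applied to
#' both wireless channels; cable events to both wired channels; listed
#' sensor-removal intervals to the wireless channels; and the wireless SpO2
#' additionally loses every period whose scheduled wireless SNR is below
#' 0 dB (cause `LOW_SNR`). Skin scores are drawn with the before-score
#' distribution concentrated on 3-4 and a change distribution supported on
#' \{-1, 0, +1\}.
#'
#' @param spec A `simulation_spec`.
#' @param context_pad_s Attribution padding the injections must respect.
#' @return A list with `recording` (a `dual_day_recording`), `truth` (list:
#'   true_bias_pct, injected_gaps, snr_schedules, oxygen_group_truth, nscs),
#'   and `skin_scores` (a two-row assessment table).
#' @export
simulate_day <- function(spec, context_pad_s = 5) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  infant_id <- sprintf("sim-%05d", spec$seed %% 100000)

  wired_ppg <- simulate_ppg(spec, "WIRED_PPG")
  wireless_ppg <- simulate_ppg(spec, "WIRELESS_PPG")
  spo2 <- simulate_spo2_pair(spec)
  fio2_vals <- schedule_at(spec$fio2_profile,
                           seq_len(round(spec$duration_s)) - 1, "fio2")
  fio2 <- ts_channel("FIO2", fio2_vals, rate = 1, start_time = 0)

  sr <- spec$sensor_removal_events
  snr_iv <- schedule_intervals(spec$wireless_snr_db, spec$duration_s,
                               "snr_db")
  low_snr <- snr_iv[snr_iv$value < 0, c("start_s", "end_s"), drop = FALSE]

  protected <- rbind(sr[, c("start_s", "end_s"), drop = FALSE], low_snr)
  bt <- drop_near(sample_poisson_intervals(spec$bt_dropout_rate_per_h,
                                           spec$bt_dropout_mean_s,
                                           spec$duration_s),
                  protected, 2 * context_pad_s)
  cable <- drop_near(sample_poisson_intervals(spec$cable_dropout_rate_per_h,
                                              spec$cable_dropout_mean_s,
                                              spec$duration_s),
                     sr[, c("start_s", "end_s"), drop = FALSE],
                     2 * context_pad_s)

  wl_iv <- rbind(bt, sr[, c("start_s", "end_s"), drop = FALSE])
  wl_causes <- c(rep("BD", nrow(bt)), rep("SR_SA", nrow(sr)))
  wl_spo2_iv <- rbind(wl_iv, low_snr)
  wl_spo2_causes <- c(wl_causes, rep("LOW_SNR", nrow(low_snr)))

  r1 <- inject_intervals(wireless_ppg, wl_iv, wl_causes)
  r2 <- inject_intervals(spo2$wireless, wl_spo2_iv, wl_spo2_causes)
  r3 <- inject_intervals(wired_ppg, cable, rep("CABLE", nrow(cable)))
  r4 <- inject_intervals(spo2$wired, cable, rep("CABLE", nrow(cable)))

  annotations <- rbind(
    annotation_events(sr$label, sr$start_s, sr$end_s),
    annotation_events(spec$care_activities$label,
                      spec$care_activities$start_s,
                      spec$care_activities$end_s))
  flags <- device_flags(rep("BT_DISCONNECT", nrow(bt)),
                        bt$start_s, bt$end_s)

  rec <- dual_day_recording(
    infant_id = infant_id, day_index = 1L,
    channels = list(WIRED_PPG = r3$channel, WIRELESS_PPG = r1$channel,
                    WIRED_SPO2 = r4$channel, WIRELESS_SPO2 = r2$channel,
                    FIO2 = fio2),
    annotations = annotations, flags = flags,
    planned_duration_s = spec$duration_s)

  before <- sample(c(3L, 4L), 1, prob = c(74, 3))
  delta <- sample(c(-1L, 0L, 1L), 1, prob = c(3, 63, 7))
  after <- min(max(before + delta, 3L), 9L)
  skin <- data.frame(infant_id = infant_id, day_index = 1L,
                     phase = c("BEFORE", "AFTER"),
                     nscs = c(before, after))

  fio2_iv <- schedule_intervals(spec$fio2_profile, spec$duration_s, "fio2")
  supp_time <- sum((fio2_iv$end_s - fio2_iv$start_s)[fio2_iv$value > 0.21])
  truth <- list(
    true_bias_pct = spec$device_bias_pct,
    injected_gaps = rbind(r1$gaps, r2$gaps, r3$gaps, r4$gaps),
    snr_schedules = list(WIRED_PPG = spec$wired_snr_db,
                         WIRELESS_PPG = spec$wireless_snr_db),
    oxygen_group_truth = if (supp_time / spec$duration_s > 0.5)
      "SUPPLEMENTAL" else "ROOM_AIR",
    nscs = skin)
  list(recording = rec, truth = truth, skin_scores = skin)
}

#' Injected gaps long enough to be detectable
#'
#' Filters a ground-truth gap table to the gaps whose duration strictly
#' exceeds the detection threshold of their channel -- the set
#' [detect_gaps()] is expected to recover exactly.
#'
#' @param injected_gaps Ground-truth gap table from [simulate_day()].
#' @param thresholds A [gap_thresholds()].
#' @return The filtered gap table.
#' @export
detectable_gaps <- function(injected_gaps, thresholds = gap_thresholds()) {
  thr <- vapply(injected_gaps$channel_id, threshold_for, numeric(1),
                thresholds = thresholds)
  injected_gaps[injected_gaps$duration_s > thr + 1e-12, , drop = FALSE]
}
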