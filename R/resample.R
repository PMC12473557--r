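# Resampling to the common analysis grid and dual-device synchronization.

#' Resample a channel to a target rate
#'
#' Puts a channel on a uniform grid at `target_rate` starting at the channel's
#' `start_time`. PPG channels are linearly interpolated between valid
#' neighbouring input samples; SpO2 and FiO2 use nearest-neighbour assignment
#' within half an input sample interval (0.5 s at 1 Hz). No values are ever
#' synthesized across missing data: an output point whose bracketing input
#' grid samples include a missing sample stays missing.
#'
#' @param channel A `ts_channel`.
#' @param target_rate Target sampling rate in Hz (> 0).
#' @return A `ts_channel` at `target_rate` spanning the same interval.
#' @export
resample_channel <- function(channel, target_rate) {
  stopifnot(inherits(channel, "ts_channel"))
  if (!is.finite(target_rate) || target_rate <= 0)
    stop("target_rate must be positive", call. = FALSE)
  n_in <- length(channel$values)
  if (n_in == 0) {
    return(ts_channel(channel$channel_id, numeric(),
                      rate = target_rate, start_time = channel$start_time,
                      units = channel$units))
  }
  if (target_rate == channel$rate) return(channel)

  duration <- n_in / channel$rate
  n_out <- round(duration * target_rate)
  t_out <- (seq_len(n_out) - 1) / target_rate          # relative to start_time
  t_in <- (seq_len(n_in) - 1) / channel$rate
  v_in <- channel$values
  ppg <- channel$channel_id %in% c("WIRED_PPG", "WIRELESS_PPG")

  if (ppg) {
    valid <- which(!is.na(v_in))
    out <- rep(NA_real_, n_out)
    if (length(valid) >= 2) {
      out <- stats::approx(t_in[valid], v_in[valid], xout = t_out,
                           method = "linear", rule = 1)$y
      # no-interpolation contract: output valid only if the input grid
      # samples bracketing it are themselves valid
      lo <- pmin(pmax(floor(t_out * channel$rate) + 1, 1), n_in)
      hi <- pmin(lo + 1, n_in)
      exact <- abs(t_out - t_in[lo]) < 1e-9
      ok <- ifelse(exact, !is.na(v_in[lo]), !is.na(v_in[lo]) & !is.na(v_in[hi]))
      out[!ok] <- NA
    } else if (length(valid) == 1) {
      hit <- which(abs(t_out - t_in[valid]) < 1e-9)
      out[hit] <- v_in[valid]
    }
  } else {
    # nearest neighbour within half the input sample interval
    win <- 0.5 / channel$rate
    idx <- round(t_out * channel$rate) + 1
    ok <- idx >= 1 & idx <= n_in
    idx[!ok] <- 1L
    out <- v_in[idx]
    out[!ok | abs(t_out - t_in[idx]) > win + 1e-12] <- NA
  }
  ts_channel(channel$channel_id, out, rate = target_rate,
             start_time = channel$start_time, units = channel$units)
}

# Put a 1 Hz channel's valid values onto an integer-second grid over
# [0, horizon); used by the synchronizer.
grid_1hz <- function(channel, horizon) {
  out <- rep(NA_real_, horizon)
  t <- channel_times(channel)
  idx <- round(t) + 1
  keep <- idx >= 1 & idx <= horizon & abs(t - round(t)) < 0.5
  out[idx[keep]] <- channel$values[keep]
  out
}

#' Estimate the wired-wireless clock offset from paired SpO2 streams
#'
#' Finds the integer-second lag in `[-max_lag_s, max_lag_s]` that maximizes
#' the cross-correlation of the mean-removed wired and wireless SpO2 traces.
#' A positive offset means the wireless stream lags (is delayed relative to)
#' the wired stream by that many seconds.
#'
#' @param wired_spo2,wireless_spo2 1 Hz `ts_channel`s.
#' @param max_lag_s Maximum absolute lag searched, seconds.
#' @param min_overlap_s Minimum seconds of jointly valid data required.
#' @return The offset in seconds (numeric scalar).
#' @export
estimate_offset <- function(wired_spo2, wireless_spo2, max_lag_s = 120,
                            min_overlap_s = 60) {
  horizon <- ceiling(max(channel_span(wired_spo2),
                         channel_span(wireless_spo2))) + max_lag_s
  a <- grid_1hz(wired_spo2, horizon)
  b <- grid_1hz(wireless_spo2, horizon)
  lags <- -max_lag_s:max_lag_s
  score <- rep(NA_real_, length(lags))
  n_ok <- integer(length(lags))
  for (k in seq_along(lags)) {
    lag <- lags[k]
    # compare a[t] with b[t + lag]
    if (lag >= 0) {
      aa <- a[seq_len(horizon - lag)]
      bb <- b[seq_len(horizon - lag) + lag]
    } else {
      aa <- a[seq_len(horizon + lag) - lag]
      bb <- b[seq_len(horizon + lag)]
    }
    ok <- !is.na(aa) & !is.na(bb)
    n_ok[k] <- sum(ok)
    if (n_ok[k] < min_overlap_s) next
    x <- aa[ok] - mean(aa[ok])
    y <- bb[ok] - mean(bb[ok])
    sx <- sqrt(sum(x^2)); sy <- sqrt(sum(y^2))
    if (sx == 0 || sy == 0) next
    score[k] <- sum(x * y) / (sx * sy)
  }
  if (all(is.na(score))) {
    if (max(n_ok) < min_overlap_s)
      stop("insufficient overlapping valid SpO2 data to estimate the offset; ",
           "pass the offset explicitly", call. = FALSE)
    stop("SpO2 traces are constant over the overlap; no identifiable ",
         "correlation peak - pass the offset explicitly", call. = FALSE)
  }
  lags[which.max(score)]
}

#' Synchronize the wireless channels of a recording to the wired clock
#'
#' Estimates a single constant offset between the devices from their SpO2
#' streams (see [estimate_offset()]) and shifts every wireless channel, flag
#' and wireless-origin annotation back by that offset. No drift model is
#' applied: the acquisition platform is assumed to have handled sample-clock
#' drift upstream.
#'
#' @param rec A `dual_day_recording`.
#' @param max_lag_s Maximum absolute lag searched, seconds.
#' @param offset_s Optional known offset; skips estimation when given.
#' @return A list with `offset_s` and the aligned `recording`.
#' @export
synchronize_recording <- function(rec, max_lag_s = 120, offset_s = NULL) {
  validate_recording(rec)
  if (is.null(offset_s)) {
    offset_s <- estimate_offset(rec$channels$WIRED_SPO2,
                                rec$channels$WIRELESS_SPO2, max_lag_s)
  }
  message(sprintf("synchronize: wireless offset %+g s relative to wired",
                  offset_s))
  shifted <- rec
  for (role in c("WIRELESS_PPG", "WIRELESS_SPO2")) {
    ch <- shifted$channels[[role]]
    ch$start_time <- ch$start_time - offset_s
    shift <- ch$start_time
    if (shift < 0) {
      drop_n <- ceiling(-shift * ch$rate - 1e-9)
      ch$values <- ch$values[-seq_len(min(drop_n, length(ch$values)))]
      ch$start_time <- ch$start_time + drop_n / ch$rate
    }
    over <- channel_span(ch) - rec$planned_duration_s
    if (over > 1e-9) {
      drop_n <- ceiling(over * ch$rate - 1e-9)
      ch$values <- ch$values[seq_len(max(length(ch$values) - drop_n, 0))]
    }
    shifted$channels[[role]] <- ch
  }
  if (nrow(shifted$flags)) {
    shifted$flags$start_s <- pmax(shifted$flags$start_s - offset_s, 0)
    shifted$flags$end_s <- pmax(shifted$flags$end_s - offset_s, 0)
  }
  validate_recording(shifted)
  list(offset_s = offset_s, recording = shifted)
}
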