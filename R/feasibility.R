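# Feasibility analysis: signal coverage, gap detection, PPG signal-to-noise
# estimation, and decision-tree gap-cause attribution.

#' Gap-detection thresholds
#'
#' A missing run only counts as a gap when its duration strictly exceeds the
#' channel's threshold: 31.25 ms (two 64 Hz samples) for PPG and 2 s for
#' SpO2/FiO2 by default.
#'
#' @param ppg_gap_s Threshold for PPG channels, seconds.
#' @param spo2_gap_s Threshold for SpO2/FiO2 channels, seconds.
#' @return A list of class `gap_thresholds`.
#' @export
gap_thresholds <- function(ppg_gap_s = 0.03125, spo2_gap_s = 2.0) {
  if (ppg_gap_s <= 0 || spo2_gap_s <= 0)
    stop("gap thresholds must be positive", call. = FALSE)
  structure(list(ppg_gap_s = ppg_gap_s, spo2_gap_s = spo2_gap_s),
            class = "gap_thresholds")
}

threshold_for <- function(channel_id, thresholds) {
  if (channel_id %in% c("WIRED_PPG", "WIRELESS_PPG")) thresholds$ppg_gap_s
  else thresholds$spo2_gap_s
}

# Missing-sample mask over the full planned grid of a channel. Slots before
# start_time or after the channel's last sample count as missing, so leading
# and trailing outages are gaps relative to the monitoring period.
planned_missing_mask <- function(channel, planned_duration_s) {
  r <- channel$rate
  n_slots <- round(planned_duration_s * r)
  miss <- rep(TRUE, n_slots)
  offset <- round(channel$start_time * r)
  idx <- seq_along(channel$values) + offset
  keep <- idx >= 1 & idx <= n_slots
  miss[idx[keep]] <- is.na(channel$values[keep])
  miss
}

#' Detect gaps in a channel
#'
#' A gap is a maximal run of missing samples -- including leading and trailing
#' missing time relative to the planned monitoring period -- whose duration
#' strictly exceeds the channel's threshold. Runs separated by even a single
#' valid sample are distinct gaps. Times are half-open `[start_s, end_s)` on
#' the channel's grid.
#'
#' @param channel A `ts_channel` on its uniform grid.
#' @param thresholds A [gap_thresholds()].
#' @param planned_duration_s Planned monitoring period, seconds.
#' @return A data.frame with columns channel_id, start_s, end_s, duration_s,
#'   cause (`NA` until attributed) and activity.
#' @export
detect_gaps <- function(channel, thresholds = gap_thresholds(),
                        planned_duration_s) {
  stopifnot(inherits(channel, "ts_channel"))
  if (planned_duration_s <= 0)
    stop("planned_duration_s must be positive", call. = FALSE)
  r <- channel$rate
  thr <- threshold_for(channel$channel_id, thresholds)
  miss <- planned_missing_mask(channel, planned_duration_s)
  empty <- data.frame(channel_id = character(), start_s = numeric(),
                      end_s = numeric(), duration_s = numeric(),
                      cause = character(), activity = character())
  if (!length(miss)) return(empty)
  runs <- rle(miss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & (runs$lengths / r > thr + 1e-12)
  if (!any(keep)) return(empty)
  data.frame(channel_id = channel$channel_id,
             start_s = (starts[keep] - 1) / r,
             end_s = ends[keep] / r,
             duration_s = runs$lengths[keep] / r,
             cause = NA_character_, activity = NA_character_)
}

#' Signal coverage of a channel
#'
#' Coverage is the percentage of the planned monitoring period during which
#' data were continuously available, i.e. 100 minus the percentage of time
#' lost to gaps. By construction coverage_pct plus the gap-time percentage
#' equals 100 exactly.
#'
#' @inheritParams detect_gaps
#' @return A one-row data.frame: channel_id, coverage_pct, total_gap_time_s,
#'   n_gaps.
#' @export
coverage <- function(channel, thresholds = gap_thresholds(),
                     planned_duration_s) {
  gaps <- detect_gaps(channel, thresholds, planned_duration_s)
  total <- sum(gaps$duration_s)
  data.frame(channel_id = channel$channel_id,
             coverage_pct = 100 * (planned_duration_s - total) /
               planned_duration_s,
             total_gap_time_s = total, n_gaps = nrow(gaps))
}

#' Estimate PPG signal-to-noise ratio over sliding windows
#'
#' For each window the periodogram of the mean-removed valid samples is
#' computed; the cardiac fundamental is located as the periodogram peak in
#' 1-4 Hz; signal power is the power within +/- `peak_halfwidth_hz` of the
#' fundamental and of its first harmonic, noise power is the remaining power
#' in 0.1-10 Hz, and SNR is their ratio in dB, capped at +/- 40 dB. Windows
#' with fewer than 50% valid samples, or with no locatable cardiac peak, get
#' a missing SNR. The estimate is invariant to overall amplitude scaling.
#'
#' @param ppg A PPG `ts_channel`.
#' @param window_s Window length, seconds.
#' @param overlap Fractional overlap between consecutive windows.
#' @param peak_halfwidth_hz Half-width of the signal bands, Hz.
#' @param cap_db Cap on |SNR|, dB.
#' @return A data.frame of class `snr_series` with columns window_center_s
#'   and snr_db; window parameters are stored as attributes.
#' @export
estimate_snr <- function(ppg, window_s = 30, overlap = 0.5,
                         peak_halfwidth_hz = 0.3, cap_db = 40) {
  stopifnot(inherits(ppg, "ts_channel"))
  r <- ppg$rate
  wlen <- round(window_s * r)
  hop <- max(1L, round(wlen * (1 - overlap)))
  n <- length(ppg$values)
  starts <- seq(1L, max(n - wlen + 1L, 1L), by = hop)
  centers <- ppg$start_time + (starts - 1 + wlen / 2) / r
  snr <- rep(NA_real_, length(starts))
  for (k in seq_along(starts)) {
    x <- ppg$values[starts[k]:min(starts[k] + wlen - 1L, n)]
    v <- x[!is.na(x)]
    if (length(v) < 0.5 * wlen) next
    v <- v - mean(v)
    m <- length(v)
    pw <- Mod(stats::fft(v))^2 / m
    freq <- (seq_len(m) - 1) * r / m
    half <- freq > 0 & freq <= r / 2
    pw <- pw[half]; freq <- freq[half]
    band <- freq >= 1 & freq <= 4
    if (!any(band) || all(pw[band] == 0)) next
    f0 <- freq[band][which.max(pw[band])]
    sig_band <- abs(freq - f0) <= peak_halfwidth_hz |
      abs(freq - 2 * f0) <= peak_halfwidth_hz
    analysis <- freq >= 0.1 & freq <= 10
    p_sig <- sum(pw[analysis & sig_band])
    p_noise <- sum(pw[analysis & !sig_band])
    snr[k] <- if (p_noise <= 0) cap_db
      else max(min(10 * log10(p_sig / p_noise), cap_db), -cap_db)
  }
  structure(data.frame(window_center_s = centers, snr_db = snr),
            class = c("snr_series", "data.frame"),
            window_s = window_s, overlap = overlap, cap_db = cap_db)
}

interval_overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & b_start < a_end
}

#' Attribute detected gaps to causes with activity context
#'
#' Applies the four-way decision tree, first matching rule wins:
#' \enumerate{
#'   \item gap overlaps a `BT_DISCONNECT` flag padded by `context_pad_s`
#'     -> `BD` (Bluetooth disconnection);
#'   \item gap overlaps an `SR`/`SA` annotation padded by `context_pad_s`
#'     -> `SR_SA` (sensor removed or adjusted);
#'   \item mean PPG SNR over the windows whose centers fall within one window
#'     length of the gap is below 0 dB -> `LOW_SNR`;
#'   \item otherwise `unknown_cause` (`UNKNOWN` by default; pass `"CABLE"`
#'     for wired channels, whose residual gaps are cable disconnections).
#' }
#' The activity label is the annotated care activity (KC/RC/PAU/O) covering
#' the gap midpoint, else `NONE`.
#'
#' @param gaps Gap table from [detect_gaps()].
#' @param flags Device-flag table.
#' @param annotations Annotation table.
#' @param snr An `snr_series` for the same device's PPG, or `NULL`.
#' @param context_pad_s Padding applied to flags/annotations, seconds.
#' @param unknown_cause Fallback cause label.
#' @return The gap table with `cause` and `activity` filled in.
#' @export
attribute_gaps <- function(gaps, flags = device_flags(),
                           annotations = annotation_events(),
                           snr = NULL, context_pad_s = 5,
                           unknown_cause = "UNKNOWN") {
  stopifnot(unknown_cause %in% GAP_CAUSES)
  if (!nrow(gaps)) return(gaps)
  window_s <- if (!is.null(snr)) attr(snr, "window_s") else 30
  bt <- flags[flags$flag_type == "BT_DISCONNECT", , drop = FALSE]
  sr <- annotations[annotations$label %in% c("SR", "SA"), , drop = FALSE]
  act <- annotations[annotations$label %in% ACTIVITY_LABELS, , drop = FALSE]
  for (i in seq_len(nrow(gaps))) {
    gs <- gaps$start_s[i]; ge <- gaps$end_s[i]
    cause <- unknown_cause
    if (nrow(bt) && any(interval_overlaps(gs, ge, bt$start_s - context_pad_s,
                                          bt$end_s + context_pad_s))) {
      cause <- "BD"
    } else if (nrow(sr) && any(interval_overlaps(gs, ge,
                                                 sr$start_s - context_pad_s,
                                                 sr$end_s + context_pad_s))) {
      cause <- "SR_SA"
    } else if (!is.null(snr)) {
      near <- snr$window_center_s >= gs - window_s &
        snr$window_center_s <= ge + window_s & !is.na(snr$snr_db)
      if (any(near) && mean(snr$snr_db[near]) < 0) cause <- "LOW_SNR"
    }
    gaps$cause[i] <- cause
    mid <- (gs + ge) / 2
    hit <- act$start_s <= mid & mid < act$end_s
    gaps$activity[i] <- if (any(hit)) act$label[which(hit)[1]] else "NONE"
  }
  gaps
}

#' Cross-tabulate gap causes by activity context
#'
#' @param gaps Attributed gap table.
#' @return A contingency table of cause by activity.
#' @export
gap_cause_table <- function(gaps) {
  table(cause = factor(gaps$cause, levels = GAP_CAUSES),
        activity = factor(gaps$activity, levels = c(ACTIVITY_LABELS, "NONE")))
}

#' Compare paired per-day metrics (Wilcoxon signed-rank)
#'
#' Convenience wrapper around [wilcoxon_signed_rank()] for paired per-day
#' metrics such as coverage: differences are `a - b` and the test is run
#' directly on them.
#'
#' @param a,b Equal-length numeric vectors of paired per-day metrics.
#' @param ... Passed to [wilcoxon_signed_rank()].
#' @return See [wilcoxon_signed_rank()].
#' @export
compare_paired <- function(a, b, ...) {
  if (length(a) != length(b))
    stop("paired comparison requires equal lengths", call. = FALSE)
  if (length(a) < 2) stop("need at least 2 pairs", call. = FALSE)
  wilcoxon_signed_rank(a - b, direction = "as_given", ...)
}

#' Compare unpaired samples (Wilcoxon rank-sum)
#'
#' Rank-sum test with mid-ranks and the normal approximation without
#' continuity correction. The statistic is the rank sum of the first sample.
#'
#' @param x,y Numeric vectors.
#' @param tie_correction Subtract the tie term from the null variance.
#' @return A list with statistic (rank sum of `x`), z, p_two_sided, n_x, n_y.
#' @export
compare_unpaired <- function(x, y, tie_correction = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group",
                             call. = FALSE)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  v <- n1 * n2 * (N + 1) / 12
  if (tie_correction) {
    t <- table(c(x, y))
    v <- v - n1 * n2 * sum(t^3 - t) / (12 * N * (N - 1))
  }
  if (v <= 0) stop("degenerate rank-sum variance (all values tied)",
                   call. = FALSE)
  z <- (W - mu) / sqrt(v)
  list(statistic = W, z = z, p_two_sided = 2 * stats::pnorm(-abs(z)),
       n_x = n1, n_y = n2)
}
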