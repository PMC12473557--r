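# Recording data model: uniform-rate channels with explicit missingness,
# annotation events, device flags, and the per-infant-day recording container.

#' Channel roles and their nominal sampling rates
#'
#' The five channel roles a dual-device recording carries, with the sampling
#' rate each role is required to have after ingestion: wired PPG at 75 Hz,
#' wireless PPG at 64 Hz, both SpO2 streams and FiO2 at 1 Hz.
#'
#' @return Named numeric vector mapping role to nominal rate in Hz.
#' @export
channel_roles <- function() {
  c(WIRED_PPG = 75, WIRELESS_PPG = 64,
    WIRED_SPO2 = 1, WIRELESS_SPO2 = 1, FIO2 = 1)
}

ANNOTATION_LABELS <- c("KC", "RC", "PAU", "SR", "SA", "O", "NONE")
ACTIVITY_LABELS <- c("KC", "RC", "PAU", "O")
FLAG_TYPES <- c("BT_DISCONNECT", "POOR_CONTACT")
GAP_CAUSES <- c("BD", "SR_SA", "LOW_SNR", "UNKNOWN", "CABLE")

#' Construct a uniform-rate time-series channel
#'
#' One signal on a uniform sampling grid. Sample `i` is located at
#' `start_time + (i - 1) / rate` seconds from the recording epoch; sample
#' intervals are half-open `[t, t + 1/rate)`. Missing samples are `NA` --
#' missingness is always explicit, never a sentinel physiological value,
#' so downstream gap analysis can distinguish "absent" from "zero".
#'
#' @param channel_id One of `names(channel_roles())`.
#' @param values Numeric vector of samples; `NA` marks a missing sample.
#' @param rate Sampling rate in Hz. Defaults to the role's nominal rate.
#' @param start_time Time of the first sample, seconds from epoch.
#' @param units Measurement units; defaults by role (arbitrary for PPG,
#'   percent for SpO2, fraction for FiO2).
#' @return An object of class `ts_channel`.
#' @export
ts_channel <- function(channel_id, values, rate = NULL, start_time = 0,
                       units = NULL) {
  channel_id <- match.arg(channel_id, names(channel_roles()))
  if (is.null(rate)) rate <- unname(channel_roles()[channel_id])
  if (is.null(units)) {
    units <- switch(channel_id,
      WIRED_PPG = , WIRELESS_PPG = "arbitrary",
      WIRED_SPO2 = , WIRELESS_SPO2 = "percent",
      FIO2 = "fraction")
  }
  x <- structure(
    list(channel_id = channel_id, start_time = as.numeric(start_time),
         rate = as.numeric(rate), values = as.numeric(values),
         units = units),
    class = "ts_channel")
  validate_channel(x)
  x
}

#' @export
print.ts_channel <- function(x, ...) {
  n <- length(x$values)
  miss <- sum(is.na(x$values))
  cat(sprintf("<ts_channel %s> %d samples @ %g Hz, start %gs, %d missing (%.1f%%)\n",
              x$channel_id, n, x$rate, x$start_time, miss,
              if (n) 100 * miss / n else 0))
  invisible(x)
}

validate_channel <- function(x) {
  stopifnot(inherits(x, "ts_channel"))
  if (!is.finite(x$rate) || x$rate <= 0)
    stop("channel rate must be a positive number", call. = FALSE)
  v <- x$values[!is.na(x$values)]
  if (x$channel_id %in% c("WIRED_SPO2", "WIRELESS_SPO2") &&
      length(v) && (min(v) < 0 || max(v) > 100))
    stop("present SpO2 values must lie in [0, 100]", call. = FALSE)
  if (x$channel_id == "FIO2" && length(v) && (min(v) < 0.21 || max(v) > 1))
    stop("present FiO2 values must lie in [0.21, 1.0]", call. = FALSE)
  invisible(x)
}

#' Sample times of a channel
#'
#' @param channel A `ts_channel`.
#' @return Numeric vector of sample times in seconds from the epoch.
#' @export
channel_times <- function(channel) {
  channel$start_time + (seq_along(channel$values) - 1) / channel$rate
}

channel_span <- function(channel) {
  channel$start_time + length(channel$values) / channel$rate
}

#' Construct an annotation-event table
#'
#' Timestamped care-activity and sensor-handling annotations. Labels follow
#' the bedside vocabulary: KC (kangaroo care), RC (routine care), PAU
#' (pause), SR/SA (sensor removed / adjusted), O (other), NONE.
#' Intervals are half-open `[start_s, end_s)`.
#'
#' @param label Character vector of labels.
#' @param start_s,end_s Interval bounds in seconds; `end_s >= start_s`.
#' @return A `data.frame` with columns label, start_s, end_s.
#' @export
annotation_events <- function(label = character(), start_s = numeric(),
                              end_s = numeric()) {
  label <- as.character(label)
  bad <- setdiff(unique(label), ANNOTATION_LABELS)
  if (length(bad))
    stop("unknown annotation label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(end_s < start_s))
    stop("annotation end_s must be >= start_s", call. = FALSE)
  data.frame(label = label, start_s = as.numeric(start_s),
             end_s = as.numeric(end_s))
}

#' Construct a device-flag table
#'
#' Automatic alerts emitted by the wireless system: `BT_DISCONNECT`
#' (Bluetooth link lost) and `POOR_CONTACT` (sensor-skin contact compromised).
#'
#' @param flag_type Character vector of flag types.
#' @param start_s,end_s Interval bounds in seconds; `end_s >= start_s`.
#' @return A `data.frame` with columns flag_type, start_s, end_s.
#' @export
device_flags <- function(flag_type = character(), start_s = numeric(),
                         end_s = numeric()) {
  flag_type <- as.character(flag_type)
  bad <- setdiff(unique(flag_type), FLAG_TYPES)
  if (length(bad))
    stop("unknown flag type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(end_s < start_s))
    stop("flag end_s must be >= start_s", call. = FALSE)
  data.frame(flag_type = flag_type, start_s = as.numeric(start_s),
             end_s = as.numeric(end_s))
}

#' Construct a dual-device infant-day recording
#'
#' The unit of analysis: all five channels (wired/wireless PPG, wired/wireless
#' SpO2, FiO2), bedside annotations, device flags, and the planned monitoring
#' duration (8 h by default) for one infant on one study day.
#'
#' @param infant_id Opaque identifier.
#' @param day_index Study day, 1-4.
#' @param channels Named list of `ts_channel`, one per role in
#'   `names(channel_roles())`.
#' @param annotations Annotation table; see [annotation_events()].
#' @param flags Device-flag table; see [device_flags()].
#' @param planned_duration_s Planned monitoring period in seconds.
#' @return An object of class `dual_day_recording`.
#' @export
dual_day_recording <- function(infant_id, day_index, channels,
                               annotations = annotation_events(),
                               flags = device_flags(),
                               planned_duration_s = 8 * 3600) {
  rec <- structure(
    list(infant_id = as.character(infant_id),
         day_index = as.integer(day_index),
         channels = channels,
         annotations = annotations, flags = flags,
         planned_duration_s = as.numeric(planned_duration_s)),
    class = "dual_day_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "dual_day_recording"))
  roles <- names(channel_roles())
  missing_roles <- setdiff(roles, names(rec$channels))
  if (length(missing_roles))
    stop("recording is missing required channel role(s): ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  if (!rec$day_index %in% 1:4)
    stop("day_index must be 1-4", call. = FALSE)
  if (rec$planned_duration_s <= 0)
    stop("planned_duration_s must be positive", call. = FALSE)
  for (role in roles) {
    ch <- rec$channels[[role]]
    validate_channel(ch)
    if (ch$channel_id != role)
      stop("channel stored under role ", role, " has channel_id ",
           ch$channel_id, call. = FALSE)
    nominal <- unname(channel_roles()[role])
    if (ch$rate != nominal)
      stop(sprintf("channel %s must be at %g Hz after ingestion (got %g)",
                   role, nominal, ch$rate), call. = FALSE)
    if (ch$start_time < 0 ||
        channel_span(ch) > rec$planned_duration_s + 1e-9)
      stop("channel ", role, " extends outside [0, planned_duration_s)",
           call. = FALSE)
  }
  invisible(rec)
}

#' @export
print.dual_day_recording <- function(x, ...) {
  cat(sprintf("<dual_day_recording> infant %s day %d, planned %gs\n",
              x$infant_id, x$day_index, x$planned_duration_s))
  for (ch in x$channels) print(ch)
  cat(sprintf("  %d annotations, %d flags\n",
              nrow(x$annotations), nrow(x$flags)))
  invisible(x)
}
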