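# Shared fixtures built in code.

# A short dual-device recording with fully valid channels.
make_tiny_recording <- function(duration_s = 60, seed = 101) {
  spec <- simulation_spec(duration_s = duration_s,
                          bt_dropout_rate_per_h = 0,
                          cable_dropout_rate_per_h = 0,
                          wireless_snr_db = 4, seed = seed)
  simulate_day(spec)$recording
}

# Skin-assessment table reproducing the published per-day pair structure:
# per-day pair counts 19/19/17/18 with changes (-1, 0, +1) of
# (1,17,1), (0,18,1), (1,14,2), (1,14,3).
make_study_skin_scores <- function() {
  day_counts <- list(`1` = c(1, 17, 1), `2` = c(0, 18, 1),
                     `3` = c(1, 14, 2), `4` = c(1, 14, 3))
  rows <- list()
  id <- 0
  for (day in names(day_counts)) {
    cnt <- day_counts[[day]]
    deltas <- rep(c(-1L, 0L, 1L), cnt)
    for (d in deltas) {
      id <- id + 1
      before <- if (d < 0) 4L else 3L
      rows[[length(rows) + 1]] <- data.frame(
        infant_id = sprintf("p%03d", id),
        day_index = as.integer(day),
        phase = c("BEFORE", "AFTER"),
        nscs = c(before, before + d))
    }
  }
  do.call(rbind, rows)
}

# Brute-force signed-rank null moments: enumerate all 2^n sign assignments
# of the ranked |d| and standardize the observed W+ against them.
brute_force_signed_rank_z <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)), length(d) <= 12)
  r <- rank(abs(d))
  n <- length(d)
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  mu <- mean(w_all)
  v <- mean((w_all - mu)^2)   # population variance over the 2^n outcomes
  (w_obs - mu) / sqrt(v)
}

# Independent error-grid oracle: per-pair if/else over the clinical states.
ega_oracle_one <- function(ref, test, group) {
  state <- function(v) {
    if (group == "ROOM_AIR") {
      if (v <= 91) "LOW" else "NORMAL"
    } else {
      if (v <= 88) "LOW" else if (v > 95) "HIGH" else "IN_RANGE"
    }
  }
  rs <- state(ref); ts <- state(test)
  if (rs == ts) {
    if (abs(test - ref) <= 5) "A" else "B"
  } else if ((rs == "LOW" && ts == "HIGH") || (rs == "HIGH" && ts == "LOW")) {
    "E"
  } else if (rs %in% c("LOW", "HIGH")) {
    "D"
  } else {
    "C"
  }
}
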