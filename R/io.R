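# Readers/writers for the columnar recording layout.
#
# A recording directory holds four tables with a fixed schema:
#   samples      (infant_id, day_index, channel_id, t_s, value, missing)
#   annotations  (label, start_s, end_s)
#   flags        (flag_type, start_s, end_s)
#   meta         (infant_id, day_index, planned_duration_s)
# Every grid slot of every channel appears as a samples row (missing rows
# carry missing = TRUE and an empty value), so the uniform grid and all
# missingness survive a round trip exactly.

recording_tables <- c("samples", "annotations", "flags", "meta")

# Full-precision CSV: doubles written with %.17g survive as.numeric exactly.
write_table_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      s <- sprintf("%.17g", out[[j]])
      s[is.na(out[[j]])] <- ""
      out[[j]] <- s
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

read_table_csv <- function(path, numeric_cols) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (nm in intersect(numeric_cols, names(df))) {
    v <- df[[nm]]
    v[v == ""] <- NA
    df[[nm]] <- as.numeric(v)
  }
  df
}

need_arrow <- function() {
  if (!requireNamespace("arrow", quietly = TRUE))
    stop("the 'arrow' package is required for the parquet dialect",
         call. = FALSE)
}

write_table <- function(df, dir, name, dialect) {
  if (dialect == "csv") {
    write_table_csv(df, file.path(dir, paste0(name, ".csv")))
  } else {
    need_arrow()
    arrow::write_parquet(df, file.path(dir, paste0(name, ".parquet")))
  }
}

read_table <- function(dir, name, dialect, numeric_cols) {
  path <- file.path(dir, paste0(name, if (dialect == "csv") ".csv" else ".parquet"))
  if (!file.exists(path))
    stop("recording table not found: ", path, call. = FALSE)
  if (dialect == "csv") {
    read_table_csv(path, numeric_cols)
  } else {
    need_arrow()
    as.data.frame(arrow::read_parquet(path))
  }
}

#' Write a dual-device recording to a directory
#'
#' Serializes the recording as long-format columnar tables in either CSV or
#' Parquet, with one row per grid slot so that [load_recording()] restores
#' every sample, annotation and flag bit-exactly.
#'
#' @param rec A `dual_day_recording`.
#' @param dir Output directory (created if needed).
#' @param dialect `"csv"` or `"parquet"`.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir, dialect = c("csv", "parquet")) {
  dialect <- match.arg(dialect)
  validate_recording(rec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- do.call(rbind, lapply(rec$channels, function(ch) {
    data.frame(infant_id = rec$infant_id, day_index = rec$day_index,
               channel_id = ch$channel_id, t_s = channel_times(ch),
               value = ch$values, missing = is.na(ch$values))
  }))
  rownames(samples) <- NULL
  write_table(samples, dir, "samples", dialect)
  write_table(rec$annotations, dir, "annotations", dialect)
  write_table(rec$flags, dir, "flags", dialect)
  write_table(data.frame(infant_id = rec$infant_id,
                         day_index = rec$day_index,
                         planned_duration_s = rec$planned_duration_s),
              dir, "meta", dialect)
  invisible(dir)
}

#' Load a dual-device recording from a directory
#'
#' Reads the columnar tables written by [write_recording()] and rebuilds a
#' validated `dual_day_recording`. Out-of-range SpO2 (outside 0-100) and
#' FiO2 (outside 0.21-1.0) values are converted to missing and counted in
#' the load report attached as `attr(rec, "load_report")`.
#'
#' @param dir Recording directory.
#' @param dialect `"csv"` or `"parquet"`.
#' @return A `dual_day_recording` with a `load_report` attribute listing the
#'   number of out-of-range samples rejected per channel.
#' @export
load_recording <- function(dir, dialect = c("csv", "parquet")) {
  dialect <- match.arg(dialect)
  samples <- read_table(dir, "samples", dialect,
                        c("day_index", "t_s", "value"))
  ann <- read_table(dir, "annotations", dialect, c("start_s", "end_s"))
  flg <- read_table(dir, "flags", dialect, c("start_s", "end_s"))
  meta <- read_table(dir, "meta", dialect,
                     c("day_index", "planned_duration_s"))
  if (dialect == "csv") samples$missing <- samples$missing == "TRUE"

  roles <- names(channel_roles())
  missing_roles <- setdiff(roles, unique(samples$channel_id))
  if (length(missing_roles))
    stop("recording is missing required channel role(s): ",
         paste(missing_roles, collapse = ", "), call. = FALSE)

  rejected <- setNames(integer(length(roles)), roles)
  channels <- list()
  for (role in roles) {
    sub <- samples[samples$channel_id == role, , drop = FALSE]
    if (is.unsorted(sub$t_s, strictly = TRUE))
      stop("non-monotone timestamps in channel ", role, call. = FALSE)
    vals <- sub$value
    vals[sub$missing] <- NA
    rate <- unname(channel_roles()[role])
    lo <- switch(role, WIRED_SPO2 = , WIRELESS_SPO2 = 0, FIO2 = 0.21, -Inf)
    hi <- switch(role, WIRED_SPO2 = , WIRELESS_SPO2 = 100, FIO2 = 1, Inf)
    bad <- !is.na(vals) & (vals < lo | vals > hi)
    rejected[role] <- sum(bad)
    vals[bad] <- NA
    channels[[role]] <- ts_channel(role, vals, rate = rate,
                                   start_time = sub$t_s[1])
  }
  rec <- dual_day_recording(
    infant_id = meta$infant_id[1], day_index = meta$day_index[1],
    channels = channels,
    annotations = ann[, c("label", "start_s", "end_s"), drop = FALSE],
    flags = flg[, c("flag_type", "start_s", "end_s"), drop = FALSE],
    planned_duration_s = meta$planned_duration_s[1])
  attr(rec, "load_report") <- list(rejected_out_of_range = rejected,
                                   n_rejected = sum(rejected))
  rec
}

#' Read or write a skin-score table
#'
#' Skin assessments are one row per (infant, day, phase) with an integer
#' Neonatal Skin Condition Score (NSCS) from 3 (intact) to 9 (very poor).
#'
#' @param path CSV file path.
#' @return `read_skin_scores`: a data.frame with columns infant_id,
#'   day_index, phase (`"BEFORE"`/`"AFTER"`) and nscs.
#' @export
read_skin_scores <- function(path) {
  df <- read_table_csv(path, c("day_index", "nscs"))
  df$day_index <- as.integer(df$day_index)
  df$nscs <- as.integer(df$nscs)
  validate_skin_scores(df)
  df
}

#' @rdname read_skin_scores
#' @param scores Skin-score data.frame.
#' @export
write_skin_scores <- function(scores, path) {
  validate_skin_scores(scores)
  write_table_csv(scores, path)
  invisible(path)
}

validate_skin_scores <- function(df) {
  req <- c("infant_id", "day_index", "phase", "nscs")
  if (!all(req %in% names(df)))
    stop("skin-score table must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (!all(df$phase %in% c("BEFORE", "AFTER")))
    stop("phase must be BEFORE or AFTER", call. = FALSE)
  if (any(!is.na(df$nscs) & (df$nscs < 3 | df$nscs > 9)))
    stop("NSCS values must lie in [3, 9]", call. = FALSE)
  invisible(df)
}
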