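# End-to-end orchestration: load or simulate recordings, run the
# feasibility / safety / accuracy analyses under one configuration, and
# write a consolidated, self-describing report.

#' Build a study configuration
#'
#' One object holding every analysis constant -- gap thresholds, alarm
#' targets, SNR estimator parameters, rank-test conventions -- plus the input
#' mode. All constants default to the framework's published values. A config
#' serializes to YAML and back losslessly via [write_study_config()] /
#' [read_study_config()].
#'
#' @param mode `"simulate"` (generate `n_days` synthetic days) or `"files"`
#'   (load recording directories listed in `paths`).
#' @param n_days Number of synthetic days when simulating.
#' @param paths Character vector of recording directories when loading.
#' @param dialect File dialect for `"files"` mode.
#' @param sim_overrides Named list of [simulation_spec()] arguments applied
#'   to every simulated day.
#' @param thresholds A [gap_thresholds()].
#' @param targets An [oxygen_targets()].
#' @param snr_window_s,snr_overlap SNR estimator parameters.
#' @param context_pad_s Attribution padding, seconds.
#' @param zero_handling,tie_correction,direction Signed-rank conventions
#'   (see [wilcoxon_signed_rank()]).
#' @param out_dir Output directory for the report bundle.
#' @param seed Master seed; all randomness flows from it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(mode = c("simulate", "files"),
                         n_days = 4, paths = character(),
                         dialect = "csv",
                         sim_overrides = list(),
                         thresholds = gap_thresholds(),
                         targets = oxygen_targets(),
                         snr_window_s = 30, snr_overlap = 0.5,
                         context_pad_s = 5,
                         zero_handling = "drop", tie_correction = FALSE,
                         direction = "before_minus_after",
                         out_dir = "neowear-report", seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, n_days = as.integer(n_days), paths = paths,
                 dialect = dialect, sim_overrides = sim_overrides,
                 thresholds = thresholds, targets = targets,
                 snr_window_s = snr_window_s, snr_overlap = snr_overlap,
                 context_pad_s = context_pad_s,
                 zero_handling = zero_handling,
                 tie_correction = tie_correction, direction = direction,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "study_config")
}

#' @rdname study_config
#' @param config A `study_config`.
#' @param path YAML file path.
#' @export
write_study_config <- function(config, path) {
  plain <- unclass(config)
  plain$thresholds <- unclass(plain$thresholds)
  plain$targets <- unclass(plain$targets)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- study_config(
    mode = raw$mode, n_days = raw$n_days,
    paths = as.character(raw$paths %||% character()),
    dialect = raw$dialect, sim_overrides = raw$sim_overrides %||% list(),
    thresholds = do.call(gap_thresholds, raw$thresholds),
    targets = do.call(oxygen_targets, raw$targets),
    snr_window_s = raw$snr_window_s, snr_overlap = raw$snr_overlap,
    context_pad_s = raw$context_pad_s,
    zero_handling = raw$zero_handling,
    tie_correction = raw$tie_correction, direction = raw$direction,
    out_dir = raw$out_dir, seed = raw$seed)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

analyze_one_day <- function(rec, config, day_label) {
  planned <- rec$planned_duration_s
  cov <- do.call(rbind, lapply(rec$channels[setdiff(names(rec$channels),
                                                    "FIO2")],
                               coverage, thresholds = config$thresholds,
                               planned_duration_s = planned))
  cov$day <- day_label
  rownames(cov) <- NULL

  snr_wired <- estimate_snr(rec$channels$WIRED_PPG,
                            window_s = config$snr_window_s,
                            overlap = config$snr_overlap)
  snr_wireless <- estimate_snr(rec$channels$WIRELESS_PPG,
                               window_s = config$snr_window_s,
                               overlap = config$snr_overlap)

  gap_one <- function(role, snr, unknown_cause) {
    g <- detect_gaps(rec$channels[[role]], config$thresholds, planned)
    attribute_gaps(g, rec$flags, rec$annotations, snr,
                   context_pad_s = config$context_pad_s,
                   unknown_cause = unknown_cause)
  }
  gaps <- rbind(gap_one("WIRED_PPG", snr_wired, "CABLE"),
                gap_one("WIRED_SPO2", snr_wired, "CABLE"),
                gap_one("WIRELESS_PPG", snr_wireless, "UNKNOWN"),
                gap_one("WIRELESS_SPO2", snr_wireless, "UNKNOWN"))
  if (nrow(gaps)) gaps$day <- day_label

  pairs <- pair_samples(rec$channels$WIRED_SPO2, rec$channels$WIRELESS_SPO2)
  agreement <- if (nrow(pairs) >= 2) {
    s <- bland_altman(pairs)
    s$day <- day_label
    s
  } else NULL
  group <- classify_oxygen_group(rec$channels$FIO2)
  list(coverage = cov, gaps = gaps, pairs = pairs, agreement = agreement,
       group = group, snr_wired = snr_wired, snr_wireless = snr_wireless)
}

#' Run the full evaluation pipeline
#'
#' Loads or simulates the configured recordings, runs coverage/gap/SNR
#' feasibility analysis, paired skin-score statistics and SpO2 agreement with
#' error-grid classification per oxygen group, and writes a report bundle
#' (CSV tables, a JSON summary whose header records the statistical
#' conventions in force, and a checksum manifest) to `config$out_dir`.
#'
#' @param config A [study_config()].
#' @return Invisibly, a list with the per-day tables and study-level
#'   summaries (`coverage`, `gaps`, `agreement`, `aggregate`, `ega`,
#'   `safety`, `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  if (config$mode == "simulate") {
    day_seeds <- sample.int(.Machine$integer.max - 1, config$n_days)
    days <- lapply(seq_len(config$n_days), function(i) {
      spec <- do.call(simulation_spec,
                      c(config$sim_overrides, list(seed = day_seeds[i])))
      sim <- simulate_day(spec, context_pad_s = config$context_pad_s)
      list(rec = sim$recording, skin = sim$skin_scores,
           label = sprintf("day%03d", i))
    })
  } else {
    if (!length(config$paths)) stop("no recording paths given", call. = FALSE)
    days <- lapply(seq_along(config$paths), function(i) {
      rec <- tryCatch(load_recording(config$paths[i], config$dialect),
                      error = function(e)
                        stop("stage load failed for recording ",
                             config$paths[i], ": ", conditionMessage(e),
                             call. = FALSE))
      list(rec = rec, skin = NULL, label = sprintf("day%03d", i))
    })
  }

  results <- lapply(days, function(d) {
    tryCatch(analyze_one_day(d$rec, config, d$label),
             error = function(e)
               stop("stage analyze failed for ", d$label, " (infant ",
                    d$rec$infant_id, "): ", conditionMessage(e),
                    call. = FALSE))
  })

  coverage_tab <- do.call(rbind, lapply(results, `[[`, "coverage"))
  gap_tab <- do.call(rbind, lapply(results, `[[`, "gaps"))
  agreement_tab <- do.call(rbind, lapply(results, `[[`, "agreement"))
  aggregate_tab <- if (!is.null(agreement_tab) && nrow(agreement_tab))
    aggregate_daily(agreement_tab) else NULL

  groups <- vapply(results, `[[`, character(1), "group")
  ega <- lapply(c(ROOM_AIR = "ROOM_AIR", SUPPLEMENTAL = "SUPPLEMENTAL"),
                function(g) {
    pool <- do.call(rbind, lapply(results[groups == g], `[[`, "pairs"))
    if (is.null(pool) || !nrow(pool)) return(NULL)
    s <- ega_summary(pool, g, config$targets)
    list(group = g, n_pairs = s$n_pairs,
         counts = as.list(s$counts),
         proportions = as.list(round(as.numeric(s$proportions), 6) |>
                                 stats::setNames(names(s$counts))))
  })

  skin <- do.call(rbind, lapply(days, `[[`, "skin"))
  safety <- NULL
  if (!is.null(skin) && nrow(skin)) {
    prs <- pair_scores(skin)
    test <- wilcoxon_signed_rank(prs$delta,
                                 zero_handling = config$zero_handling,
                                 tie_correction = config$tie_correction,
                                 direction = config$direction)
    safety <- list(n_pairs = nrow(prs), test = test,
                   delta_counts = as.list(table(prs$delta)))
  }

  files <- character()
  emit <- function(df, name) {
    if (is.null(df) || !nrow(df)) return()
    p <- file.path(config$out_dir, name)
    write_table_csv(df, p)
    files <<- c(files, p)
  }
  emit(coverage_tab, "coverage.csv")
  emit(gap_tab, "gaps.csv")
  emit(agreement_tab, "agreement.csv")
  emit(aggregate_tab, "aggregate.csv")

  summary <- list(
    conventions = list(
      gap_thresholds = unclass(config$thresholds),
      oxygen_targets = unclass(config$targets),
      snr = list(window_s = config$snr_window_s,
                 overlap = config$snr_overlap, cap_db = 40),
      signed_rank = list(zero_handling = config$zero_handling,
                         tie_correction = config$tie_correction,
                         direction = config$direction,
                         continuity = FALSE),
      difference_direction = "wired_minus_wireless",
      loa_multiplier = 1.96,
      context_pad_s = config$context_pad_s,
      seed = config$seed),
    n_days = length(days),
    oxygen_groups = as.list(table(groups)),
    aggregate = if (!is.null(aggregate_tab)) aggregate_tab else NULL,
    ega = Filter(Negate(is.null), ega),
    safety = safety)
  summary_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  files <- c(files, summary_path)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  write_table_csv(manifest, file.path(config$out_dir, "manifest.csv"))
  files <- c(files, file.path(config$out_dir, "manifest.csv"))

  invisible(list(coverage = coverage_tab, gaps = gap_tab,
                 agreement = agreement_tab, aggregate = aggregate_tab,
                 ega = ega, safety = safety, files = files))
}
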