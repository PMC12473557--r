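# Skin-safety analysis: pairing of before/after Neonatal Skin Condition
# Scores and the Wilcoxon signed-rank test with explicit conventions.

#' Pair before/after skin assessments
#'
#' Forms one paired difference per (infant, day) that has both a BEFORE and
#' an AFTER assessment; assessments lacking their counterpart are listed in
#' the `unpaired` attribute rather than silently dropped.
#'
#' @param assessments Data.frame with columns infant_id, day_index, phase
#'   (`"BEFORE"`/`"AFTER"`) and nscs (integer 3-9).
#' @return A data.frame with columns infant_id, day_index, nscs_before,
#'   nscs_after and delta (= after - before, in `[-6, 6]`), plus attributes
#'   `unpaired` (the unmatched rows) and `summary` (counts of decreases,
#'   no-change and increases with percentages over both the pair count and
#'   the assessment count, since either denominator may be wanted).
#' @export
pair_scores <- function(assessments) {
  validate_skin_scores(assessments)
  key <- paste(assessments$infant_id, assessments$day_index,
               assessments$phase)
  if (anyDuplicated(key))
    stop("duplicate (infant, day, phase) assessment(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  before <- assessments[assessments$phase == "BEFORE", , drop = FALSE]
  after <- assessments[assessments$phase == "AFTER", , drop = FALSE]
  m <- merge(before[, c("infant_id", "day_index", "nscs")],
             after[, c("infant_id", "day_index", "nscs")],
             by = c("infant_id", "day_index"),
             suffixes = c("_before", "_after"))
  m <- m[order(m$infant_id, m$day_index), , drop = FALSE]
  rownames(m) <- NULL
  m$delta <- m$nscs_after - m$nscs_before
  paired_key <- paste(m$infant_id, m$day_index)
  unpaired <- assessments[!paste(assessments$infant_id,
                                 assessments$day_index) %in% paired_key, ,
                          drop = FALSE]
  n_assess <- nrow(assessments)
  counts <- c(decrease = sum(m$delta < 0), no_change = sum(m$delta == 0),
              increase = sum(m$delta > 0))
  attr(m, "unpaired") <- unpaired
  attr(m, "summary") <- list(
    n_pairs = nrow(m), n_assessments = n_assess, counts = counts,
    pct_of_pairs = if (nrow(m)) 100 * counts / nrow(m) else counts * NA,
    pct_of_assessments = if (n_assess) 100 * counts / n_assess
      else counts * NA)
  m
}

#' Wilcoxon signed-rank test with explicit conventions
#'
#' Large-sample signed-rank test on paired score differences. The default
#' conventions -- zeros dropped, mid-ranks on tied absolute differences, no
#' tie correction of the null variance, no continuity correction, and the
#' test direction taken as before-minus-after -- are each configurable.
#'
#' With `zero_handling = "drop"`, zero differences are removed and the
#' remaining n differences ranked by absolute value with mid-ranks; W+ is the
#' rank sum of the positive differences and
#' \deqn{z = (W^+ - n(n+1)/4) / \sqrt{n(n+1)(2n+1)/24 - c_t}}
#' where the tie term \eqn{c_t = \sum_g (t_g^3 - t_g)/48} is subtracted only
#' when `tie_correction = TRUE`. With `zero_handling = "pratt"`, zeros are
#' ranked but excluded from W+ and the null moments adjusted accordingly.
#'
#' @param deltas Numeric vector of paired differences, oriented as
#'   after-minus-before (the natural orientation of a before/after table).
#' @param zero_handling `"drop"` (default) or `"pratt"`.
#' @param tie_correction Subtract the tie term from the null variance.
#' @param direction `"before_minus_after"` (default; the test statistic is
#'   computed on the negated deltas) or `"after_minus_before"`.
#' @param continuity Apply a 0.5 continuity correction toward the mean.
#' @return A list with w_plus, z, p_two_sided, n_used (differences entering
#'   the ranking after zero handling) and n_nonzero. When every difference is
#'   zero the result has `n_nonzero = 0`, `z = NA` and a `note` field rather
#'   than an error: the data carry no information about a shift.
#' @export
wilcoxon_signed_rank <- function(deltas,
                                 zero_handling = c("drop", "pratt"),
                                 tie_correction = FALSE,
                                 direction = c("before_minus_after",
                                               "after_minus_before",
                                               "as_given"),
                                 continuity = FALSE) {
  zero_handling <- match.arg(zero_handling)
  direction <- match.arg(direction)
  d <- as.numeric(deltas[!is.na(deltas)])
  if (direction == "before_minus_after") d <- -d
  n_nonzero <- sum(d != 0)
  if (n_nonzero == 0) {
    return(list(w_plus = 0, z = NA_real_, p_two_sided = NA_real_,
                n_used = 0L, n_nonzero = 0L,
                note = "all differences are zero; no usable pairs"))
  }
  if (zero_handling == "drop") {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w_plus <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    v <- n * (n + 1) * (2 * n + 1) / 24
    if (tie_correction) {
      t <- table(abs(d))
      v <- v - sum(t^3 - t) / 48
    }
  } else {
    n <- length(d)
    n0 <- sum(d == 0)
    r <- rank(abs(d))
    w_plus <- sum(r[d > 0])
    mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
    v <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24
    if (tie_correction) {
      t <- table(abs(d[d != 0]))
      v <- v - sum(t^3 - t) / 48
    }
  }
  if (v <= 0)
    return(list(w_plus = w_plus, z = NA_real_, p_two_sided = NA_real_,
                n_used = as.integer(n), n_nonzero = as.integer(n_nonzero),
                note = "degenerate null variance"))
  num <- w_plus - mu
  if (continuity) num <- num - sign(num) * 0.5
  z <- num / sqrt(v)
  list(w_plus = w_plus, z = z, p_two_sided = 2 * stats::pnorm(-abs(z)),
       n_used = as.integer(n), n_nonzero = as.integer(n_nonzero))
}

#' Tabulate skin scores in the study's report shape
#'
#' @param assessments Skin-assessment data.frame.
#' @return A list with `scores` (count of each NSCS value by day and phase)
#'   and `deltas` (count of each paired change by day).
#' @export
skin_score_tables <- function(assessments) {
  pairs <- pair_scores(assessments)
  scores <- table(day = assessments$day_index, phase = assessments$phase,
                  nscs = assessments$nscs)
  deltas <- table(day = pairs$day_index,
                  delta = factor(pairs$delta, levels = -6:6))
  list(scores = scores, deltas = deltas[, colSums(deltas) > 0, drop = FALSE])
}
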