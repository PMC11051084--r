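# Learner speed factors and speed-adjusted classification.

#' Per-learner, per-stratum speed factors
#'
#' A learner's speed factor for one stratum is the ratio of the learner's
#' total duration over their interactions in that stratum to the total of
#' the cohort item-level mean durations over those same interactions (an
#' item encountered twice contributes its mean twice, mirroring the
#' numerator). A factor of 1 means exactly-average pace; 0.5 means twice
#' as fast as average.
#'
#' Learners with fewer than `min_interactions` records in a stratum get
#' factor 1 (a factor estimated from one or two interactions would make
#' those very records unflaggable in expectation). Interactions whose
#' (item, stratum) has no entry in `stats` are excluded from both sums and
#' counted in the `n_missing_stats` column.
#'
#' @param records Stratified records.
#' @param stats Item-level statistics from [stratum_stats()] (computed on
#'   the cohort the factors should be relative to; for a restricted
#'   analysis, recompute stats on the restricted records).
#' @param min_interactions Minimum records per (learner, stratum) for a
#'   learner-specific factor (default 3).
#' @return data.table `learner_id`, `stratum`, `factor_s`,
#'   `n_interactions`, `n_missing_stats`.
#' @export
#' @examples
#' # a learner taking 20, 20 and 30 s on items whose cohort means are
#' # 20, 40 and 60 s has speed factor (20+20+30)/(20+40+60) = 0.58333
compute_speed_factors <- function(records, stats, min_interactions = 3L) {
  dt <- data.table::as.data.table(records)
  st <- data.table::as.data.table(stats)
  stopifnot(nrow(dt) > 0L, min_interactions >= 1L,
            all(c("learner_id", "item_id", "stratum", "duration") %in% names(dt)),
            all(c("item_id", "stratum", "mean_dur") %in% names(st)))
  work <- dt[, .(learner_id, item_id, stratum, duration)]
  work[st, on = c("item_id", "stratum"), mean_dur := i.mean_dur]
  out <- work[, .(
    n_interactions = sum(!is.na(mean_dur)),
    n_missing_stats = sum(is.na(mean_dur)),
    dur_sum = sum(duration[!is.na(mean_dur)]),
    mean_sum = sum(mean_dur, na.rm = TRUE)
  ), by = .(learner_id, stratum)]
  out[, factor_s := data.table::fifelse(
    n_interactions >= min_interactions & mean_sum > 0,
    dur_sum / mean_sum, 1)]
  out[, `:=`(dur_sum = NULL, mean_sum = NULL)]
  data.table::setorder(out, learner_id, stratum)
  out[]
}

#' Classify interruptions with speed-adjusted thresholds
#'
#' As [classify_interruptions()], but each record's threshold is first
#' multiplied by its learner's speed factor for the record's stratum:
#' flagged iff duration > s * T (strict). A fast learner (s < 1) gets a
#' lower threshold, so briefer interruptions are caught; a slow learner
#' (s > 1) is not penalised for pace. Learners absent from `factors`
#' default to s = 1.
#'
#' @param records Stratified records.
#' @param thresholds Output of [duration_thresholds()].
#' @param factors Output of [compute_speed_factors()].
#' @return A `"lapse_classification"` (method `"speed_adjusted"`).
#' @export
classify_adjusted <- function(records, thresholds, factors) {
  .classify_threshold(records, thresholds, factors = factors,
                      method = "speed_adjusted")
}

#' Restrict an event log to a sub-cohort
#'
#' Selects records by module, item, learner and/or a UTC time window.
#' Downstream statistics, speed factors and classifications must then be
#' recomputed on the subset: restriction changes the cohort that "average
#' pace" refers to.
#'
#' @param records Records table.
#' @param modules,items,learners Optional character vectors of ids to keep.
#' @param window Optional length-2 `"YYYY-MM"` character vector; keeps
#'   records whose `start_time` falls in the inclusive month range.
#' @return The record subset (error if empty: every downstream statistic
#'   would be undefined).
#' @export
restrict_cohort <- function(records, modules = NULL, items = NULL,
                            learners = NULL, window = NULL) {
  dt <- data.table::as.data.table(records)
  keep <- rep(TRUE, nrow(dt))
  if (!is.null(modules)) keep <- keep & dt$module_id %in% modules
  if (!is.null(items)) keep <- keep & dt$item_id %in% items
  if (!is.null(learners)) keep <- keep & dt$learner_id %in% learners
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    keep <- keep & dt$start_time >= .month_start(window[1]) &
      dt$start_time < .month_end(window[2])
  }
  if (!any(keep)) stop("cohort restriction selected no records")
  dt[keep][]
}
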