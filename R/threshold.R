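# Mean + k SD duration-outlier classifier, per item x stratum.

#' Per item-and-stratum duration statistics
#'
#' Sample mean, sample (n-1) SD, and median of duration for every
#' (item, stratum) group, computed over all records of the group including
#' any outliers (outliers inflate these statistics by construction; the
#' robust classifier exists for exactly that reason).
#'
#' @param records A stratified records table (see [derive_strata()]).
#' @return data.table with columns `item_id`, `stratum`, `n`, `mean_dur`,
#'   `sd_dur` (0 for singleton groups), `median_dur`.
#' @export
stratum_stats <- function(records) {
  dt <- data.table::as.data.table(records)
  stopifnot(nrow(dt) > 0L,
            all(c("item_id", "stratum", "duration") %in% names(dt)),
            all(dt$duration > 0))
  out <- dt[, .(n = .N, mean_dur = mean(duration),
                sd_dur = if (.N > 1L) sd(duration) else 0,
                median_dur = median(duration)),
            by = .(item_id, stratum)]
  data.table::setorder(out, item_id, stratum)
  out[]
}

#' Mean + k SD interruption thresholds
#'
#' Threshold T = mean + k * SD per (item, stratum). Groups with fewer than
#' `min_n` records get no usable threshold: their records are excluded from
#' classification and surfaced in the rejects channel, because an SD from a
#' handful of observations is not meaningful.
#'
#' @param stats Output of [stratum_stats()] (or any table with `item_id`,
#'   `stratum`, `n`, `mean_dur`, `sd_dur`).
#' @param k Multiplier on the SD (default 2).
#' @param min_n Minimum group size for a usable threshold (default 5).
#' @return data.table `item_id`, `stratum`, `threshold`, `usable`, plus
#'   attributes `k` and `min_n`.
#' @export
#' @examples
#' s <- data.frame(item_id = "Q1", stratum = "initial_attempt",
#'                 n = 37521, mean_dur = 54.60, sd_dur = 98.96)
#' duration_thresholds(s)$threshold  # 252.52
duration_thresholds <- function(stats, k = 2, min_n = 5L) {
  st <- data.table::as.data.table(stats)
  stopifnot(nrow(st) > 0L, k > 0,
            all(c("item_id", "stratum", "n", "mean_dur", "sd_dur") %in% names(st)))
  out <- st[, .(item_id, stratum, threshold = mean_dur + k * sd_dur,
                usable = n >= min_n)]
  data.table::setattr(out, "k", k)
  data.table::setattr(out, "min_n", as.integer(min_n))
  out[]
}

# Shared classification engine: flagged iff duration > s * T (strict).
# factors = NULL means s = 1 everywhere (the unadjusted classifier).
.classify_threshold <- function(records, thresholds, factors, method) {
  dt <- data.table::as.data.table(records)
  th <- data.table::as.data.table(thresholds)
  stopifnot(all(c("item_id", "stratum", "duration") %in% names(dt)),
            all(c("item_id", "stratum", "threshold") %in% names(th)))
  work <- dt[, .(item_id, stratum, duration,
                 learner_id = if ("learner_id" %in% names(dt)) learner_id else NA_character_)]
  work[, .row := .I]
  if (!"usable" %in% names(th)) th <- data.table::copy(th)[, usable := TRUE]
  work[th, on = c("item_id", "stratum"),
       `:=`(threshold = i.threshold, usable = i.usable)]
  work[, factor_s := 1]
  if (!is.null(factors)) {
    fx <- data.table::as.data.table(factors)
    stopifnot(all(c("learner_id", "stratum", "factor_s") %in% names(fx)),
              all(fx$factor_s > 0))
    work[fx, on = c("learner_id", "stratum"), factor_s := i.factor_s]
  }
  rejected <- is.na(work$threshold) | !work$usable
  applied <- work$factor_s * work$threshold
  flagged <- !rejected & work$duration > applied
  n_classified <- sum(!rejected)
  structure(list(
    method = method,
    flagged = flagged,
    applied_threshold = applied,
    rejected = rejected,
    n_flagged = sum(flagged),
    n_classified = n_classified,
    n_rejected = sum(rejected),
    rate = if (n_classified > 0) sum(flagged) / n_classified else NA_real_
  ), class = "lapse_classification")
}

#' Classify interruptions by fixed mean + k SD thresholds
#'
#' A record is flagged as an interruption iff its duration strictly
#' exceeds the threshold for its (item, stratum). Records whose group has
#' no usable threshold are rejected: excluded from the denominator and
#' counted in `n_rejected`, never silently dropped.
#'
#' @param records Stratified records.
#' @param thresholds Output of [duration_thresholds()].
#' @return A `"lapse_classification"`: per-record `flagged`,
#'   `applied_threshold` and `rejected` vectors (aligned with `records`
#'   rows), counts, and `rate` = flagged / classified.
#' @seealso [classify_adjusted()] for the speed-factor variant,
#'   [classify_modified_z()] for the robust variant.
#' @export
classify_interruptions <- function(records, thresholds) {
  .classify_threshold(records, thresholds, factors = NULL,
                      method = "mean_k_sd")
}

#' @export
print.lapse_classification <- function(x, ...) {
  cat(sprintf("<lapse_classification:%s> %d/%d flagged (rate %.4g)%s\n",
              x$method, x$n_flagged, x$n_classified, x$rate,
              if (x$n_rejected) sprintf(", %d rejected", x$n_rejected) else ""))
  invisible(x)
}

#' Interrupted share of logged time per module attempt
#'
#' For each learner x module attempt, the share of total logged duration
#' contributed by flagged records; the unweighted mean share across module
#' attempts is reported alongside (durations are positive, so the share is
#' always defined).
#'
#' @param records The records the classification was computed on.
#' @param classification A `"lapse_classification"` aligned with `records`.
#' @return list with `per_module` (learner_id, module_id, share,
#'   total_duration) and `mean_share`.
#' @export
time_share <- function(records, classification) {
  dt <- data.table::as.data.table(records)
  stopifnot(inherits(classification, "lapse_classification"),
            length(classification$flagged) == nrow(dt))
  work <- dt[, .(learner_id, module_id, duration)]
  work[, flagged := classification$flagged]
  per <- work[, .(share = sum(duration[flagged]) / sum(duration),
                  total_duration = sum(duration)),
              by = .(learner_id, module_id)]
  list(per_module = per[], mean_share = mean(per$share))
}
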