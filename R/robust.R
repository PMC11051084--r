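# Robust classifier: modified Z-scores of log, speed-adjusted durations.

#' Speed-adjusted natural-log durations
#'
#' x = ln(duration / s), where s is the learner's speed factor for the
#' record's stratum (1 if absent). Dividing by the speed factor is the
#' same normalisation as multiplying the threshold by it in the
#' speed-adjusted classifier; the log transform then tames the strong
#' right skew so a location/scale outlier rule is sensible.
#'
#' @param records Stratified records with positive durations.
#' @param factors Optional [compute_speed_factors()] table; `NULL` means
#'   s = 1 for everyone.
#' @return Numeric vector of x values aligned with `records` rows.
#' @export
adjusted_log_durations <- function(records, factors = NULL) {
  dt <- data.table::as.data.table(records)
  stopifnot(all(dt$duration > 0))
  s <- rep(1, nrow(dt))
  if (!is.null(factors)) {
    fx <- data.table::as.data.table(factors)
    stopifnot(all(fx$factor_s > 0))
    work <- dt[, .(learner_id, stratum)]
    work[, .row := .I]
    work[fx, on = c("learner_id", "stratum"), factor_s := i.factor_s]
    s[!is.na(work$factor_s)] <- work$factor_s[!is.na(work$factor_s)]
  }
  log(dt$duration / s)
}

#' Median absolute deviation (unscaled)
#'
#' MAD = med(|x_i - med(x)|); the median of an even count is the midpoint
#' of the two central order statistics. Deliberately *not* multiplied by
#' the 1.4826 normal-consistency constant: the modified Z-score carries
#' its own 0.6745 coefficient instead.
#'
#' @param x Nonempty numeric vector.
#' @return The unscaled MAD.
#' @export
#' @examples
#' mad_raw(c(1, 2, 3, 4, 9))  # 1
mad_raw <- function(x) {
  stopifnot(length(x) > 0L, is.numeric(x))
  stats::mad(x, constant = 1)
}

#' Robust location/scale per item and stratum
#'
#' Median and unscaled MAD of x = ln(duration / s) per (item, stratum).
#' Groups smaller than `min_n` are marked unusable, like small groups in
#' [duration_thresholds()].
#'
#' @inheritParams adjusted_log_durations
#' @param min_n Minimum group size (default 5).
#' @return data.table `item_id`, `stratum`, `n`, `median_x`, `mad_x`,
#'   `usable`.
#' @export
robust_stats <- function(records, factors = NULL, min_n = 5L) {
  dt <- data.table::as.data.table(records)
  stopifnot(nrow(dt) > 0L)
  work <- dt[, .(item_id, stratum)]
  work[, x := adjusted_log_durations(dt, factors)]
  out <- work[, .(n = .N, median_x = median(x), mad_x = mad_raw(x)),
              by = .(item_id, stratum)]
  out[, usable := n >= min_n]
  data.table::setorder(out, item_id, stratum)
  out[]
}

#' Classify interruptions by modified Z-score
#'
#' Each record's score is M = 0.6745 * (x - med(x)) / MAD with x the
#' speed-adjusted log duration and med/MAD taken over the record's
#' (item, stratum) group. Records with M strictly above `cutoff` are
#' flagged; the rule is one-sided (anomalously *fast* interactions are a
#' different phenomenon and are never flagged). Groups with MAD = 0 are
#' degenerate: more than half their mass sits at the median, no record is
#' flagged, and the group is counted in `n_degenerate`.
#'
#' @param records Stratified records.
#' @param factors Optional speed factors (see [compute_speed_factors()]).
#' @param stats Optional precomputed [robust_stats()]; computed from
#'   `records` and `factors` when `NULL`.
#' @param cutoff Modified Z-score cutoff (default 3.5).
#' @param min_n Minimum group size, used only when `stats` is `NULL`.
#' @return A `"lapse_classification"` (method `"modified_z"`) with an
#'   extra `score` element (per-record M, NA where rejected) and
#'   `n_degenerate` (count of MAD-0 groups among usable ones).
#' @export
classify_modified_z <- function(records, factors = NULL, stats = NULL,
                                cutoff = 3.5, min_n = 5L) {
  dt <- data.table::as.data.table(records)
  if (is.null(stats)) stats <- robust_stats(dt, factors, min_n = min_n)
  st <- data.table::as.data.table(stats)
  stopifnot(cutoff > 0,
            all(c("item_id", "stratum", "median_x", "mad_x") %in% names(st)))
  if (!"usable" %in% names(st)) st <- data.table::copy(st)[, usable := TRUE]
  work <- dt[, .(item_id, stratum)]
  work[, x := adjusted_log_durations(dt, factors)]
  work[st, on = c("item_id", "stratum"),
       `:=`(median_x = i.median_x, mad_x = i.mad_x, usable = i.usable)]
  rejected <- is.na(work$median_x) | !work$usable
  score <- rep(NA_real_, nrow(work))
  ok <- !rejected & work$mad_x > 0
  score[ok] <- 0.6745 * (work$x[ok] - work$median_x[ok]) / work$mad_x[ok]
  # MAD = 0 groups keep score NA and flag nothing (refuse to divide by 0)
  flagged <- !rejected & !is.na(score) & score > cutoff
  n_classified <- sum(!rejected)
  structure(list(
    method = "modified_z",
    flagged = flagged,
    score = score,
    rejected = rejected,
    n_flagged = sum(flagged),
    n_classified = n_classified,
    n_rejected = sum(rejected),
    n_degenerate = nrow(st[usable == TRUE & mad_x == 0]),
    rate = if (n_classified > 0) sum(flagged) / n_classified else NA_real_
  ), class = "lapse_classification")
}
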