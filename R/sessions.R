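# Session reconstruction from inactivity gaps; long-interruption counting.

#' Partition module attempts into digital sessions
#'
#' Within each learner x module attempt (interactions sorted by start
#' time), the inactivity gap before interaction i+1 is
#' `start[i+1] - (start[i] + duration[i])`. A gap of at least
#' `timeout_minutes` ends the session (the platform logs the learner out
#' at exactly the timeout, so the boundary counts). A module completed in
#' s sessions therefore had s - 1 long interruptions; only completed
#' modules contribute long interruptions — an incomplete attempt's last
#' session may simply not have ended yet — and are reported separately.
#' Attempts containing overlapping records (negative gap) are quarantined
#' with a reason rather than partitioned.
#'
#' @param records Records table with `completed` either as a column or
#'   supplied via `completions` (see [group_module_attempts()]).
#' @param timeout_minutes Inactivity timeout in minutes (default 30).
#' @param completions Optional completion marks table.
#' @return list with `attempts` (per learner x module: `n_interactions`,
#'   `session_count`, `completed`, `long_interruptions` — NA when not
#'   completed) and `quarantined` (attempt keys with reasons).
#' @export
#' @examples
#' # one 31-minute gap splits an attempt into 2 sessions
partition_sessions <- function(records, timeout_minutes = 30,
                               completions = NULL) {
  dt <- data.table::as.data.table(records)
  stopifnot(nrow(dt) > 0L, timeout_minutes > 0,
            all(c("learner_id", "module_id", "start_time", "duration") %in% names(dt)))
  ga <- group_module_attempts(dt, completions)
  work <- dt[order(start_time),
             .(start_time, duration), by = .(learner_id, module_id)]
  work[, gap := as.numeric(start_time) -
         data.table::shift(as.numeric(start_time) + duration),
       by = .(learner_id, module_id)]
  tau <- timeout_minutes * 60
  per <- work[, .(session_count = 1L + sum(gap >= tau, na.rm = TRUE),
                  negative_gap = any(gap < 0, na.rm = TRUE)),
              by = .(learner_id, module_id)]
  attempts <- ga$attempts[per, on = c("learner_id", "module_id")]
  quarantined <- attempts[negative_gap == TRUE,
                          .(learner_id, module_id,
                            reason = "overlapping records (negative gap)")]
  attempts <- attempts[negative_gap == FALSE]
  attempts[, negative_gap := NULL]
  attempts[, long_interruptions := data.table::fifelse(
    completed, session_count - 1L, NA_integer_)]
  list(attempts = attempts[], quarantined = quarantined[])
}

#' Long-interruption rate
#'
#' Sum of long-interruption counts over completed module attempts divided
#' by the total number of interactions in scope. The optional window
#' restricts both numerator and denominator to records (and attempts
#' starting) in an inclusive `"YYYY-MM"` month range, mirroring
#' analysis-window truncation for data-quality reasons.
#'
#' @param partitions Output of [partition_sessions()].
#' @param records The records defining the interaction denominator.
#' @param window Optional length-2 `"YYYY-MM"` range.
#' @return list `rate`, `long_interruptions`, `interactions`.
#' @export
long_interruption_rate <- function(partitions, records, window = NULL) {
  att <- data.table::as.data.table(partitions$attempts)
  dt <- data.table::as.data.table(records)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    lo <- .month_start(window[1]); hi <- .month_end(window[2])
    att <- att[first_start >= lo & first_start < hi]
    dt <- dt[start_time >= lo & start_time < hi]
  }
  n_int <- nrow(dt)
  if (n_int == 0L) stop("no interactions in scope; rate undefined")
  n_long <- sum(att[completed == TRUE, long_interruptions])
  list(rate = n_long / n_int,
       long_interruptions = as.integer(n_long),
       interactions = n_int)
}
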