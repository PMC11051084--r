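# Event-log data model: reading, validation, stratum derivation, grouping.

.required_cols <- c("learner_id", "item_id", "module_id", "kind",
                    "start_time", "duration_s")
.optional_cols <- c("encounter_index", "completed")

.parse_time <- function(x) {
  # ISO-8601, seconds resolution, interpreted in UTC. Parsed per element
  # (a single malformed row must reject that row, not the whole column).
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  for (f in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    miss <- is.na(out) & !is.na(x)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], f, tz = "UTC"))
  }
  out
}

#' Read a tabular interaction event log
#'
#' Reads a delimited file with one row per timed interaction. Required
#' columns: `learner_id`, `item_id`, `module_id`, `kind` (one of
#' [lapse_kinds()]), `start_time` (ISO-8601, interpreted as UTC) and
#' `duration_s` (positive seconds). Optional: `encounter_index`,
#' `completed`. Rows that fail validation are never silently dropped: they
#' are returned in a separate `rejects` table with a `reason` column.
#'
#' @param path Path to a delimited text file with a header.
#' @param columns Optional named character vector mapping the required
#'   column names to the names used in the file, e.g.
#'   `c(learner_id = "user", duration_s = "secs")`.
#' @return A list with elements `records` (validated
#'   [data.table::data.table] of interactions, `start_time` parsed to
#'   POSIXct UTC, `duration` numeric seconds) and `rejects` (the offending
#'   input rows plus `reason`).
#' @seealso [write_eventlog()], [validate_eventlog()], [derive_strata()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("learner_id,item_id,module_id,kind,start_time,duration_s",
#'              "L1,I1,M1,attempt,2021-05-01T10:00:00,30",
#'              "L1,I1,M1,feedback_review,2021-05-01T10:01:00,12"), f)
#' log <- read_eventlog(f)
#' nrow(log$records)
read_eventlog <- function(path, columns = NULL) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  raw <- data.table::fread(path, colClasses = "character",
                           na.strings = c("NA", ""))
  if (!is.null(columns)) {
    bad <- setdiff(names(columns), c(.required_cols, .optional_cols))
    if (length(bad)) stop("unknown columns mapping target(s): ",
                          paste(bad, collapse = ", "))
    have <- columns[unname(columns) %in% names(raw)]
    data.table::setnames(raw, unname(have), names(have))
  }
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols)) {
    stop("event log is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_eventlog(raw)
}

#' Validate raw event-log rows
#'
#' Partitions raw rows into validated interaction records and rejects, so
#' that every input row lands in exactly one of the two tables.
#'
#' @param raw A data.frame of character (or already typed) columns with at
#'   least the required event-log columns.
#' @return A list `records` / `rejects` as in [read_eventlog()].
#' @export
validate_eventlog <- function(raw) {
  dt <- data.table::as.data.table(raw)
  missing_cols <- setdiff(.required_cols, names(dt))
  if (length(missing_cols)) {
    stop("event log is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(dt)
  reason <- character(n)
  add_reason <- function(bad, why) {
    bad <- bad & !nzchar(reason)  # first failure wins
    reason[bad] <<- why
  }

  st <- if (inherits(dt$start_time, "POSIXct")) {
    as.POSIXct(dt$start_time, tz = "UTC")
  } else {
    .parse_time(as.character(dt$start_time))
  }
  dur <- suppressWarnings(as.numeric(dt$duration_s))
  enc <- if ("encounter_index" %in% names(dt)) {
    suppressWarnings(as.integer(dt$encounter_index))
  } else {
    rep(NA_integer_, n)
  }

  add_reason(is.na(dt$learner_id) | is.na(dt$item_id) | is.na(dt$module_id),
             "missing identifier")
  add_reason(!(dt$kind %in% lapse_kinds()), "unknown interaction kind")
  add_reason(is.na(st), "unparseable start_time")
  add_reason(is.na(dur), "unparseable duration")
  add_reason(!is.na(dur) & dur <= 0, "nonpositive duration")
  if ("encounter_index" %in% names(dt)) {
    add_reason(!is.na(dt$encounter_index) & is.na(enc),
               "unparseable encounter_index")
    add_reason(!is.na(enc) & enc < 1L, "encounter_index below 1")
  }

  ok <- !nzchar(reason)
  records <- dt[ok]
  records[, `:=`(start_time = st[ok], duration = dur[ok])]
  records[, duration_s := NULL]
  if ("encounter_index" %in% names(records)) {
    records[, encounter_index := enc[ok]]
  }
  if ("completed" %in% names(records)) {
    records[, completed := as.logical(completed)]
  }
  rejects <- dt[!ok]
  rejects[, reason := reason[!ok]]
  list(records = records[], rejects = rejects[])
}

#' Write an event log (and optional rejects) to CSV
#'
#' Timestamps are serialised as ISO-8601 UTC so that
#' `read_eventlog(write_eventlog(x))` round-trips exactly at seconds
#' resolution.
#'
#' @param records A validated records table (as from [read_eventlog()] or
#'   [simulate_eventlog()]).
#' @param path Output CSV path.
#' @param rejects Optional rejects table; written next to `path` with
#'   suffix `"_rejects.csv"`.
#' @return `path`, invisibly.
#' @export
write_eventlog <- function(records, path, rejects = NULL) {
  out <- data.table::as.data.table(records)
  out <- data.table::copy(out)
  out[, start_time := format(start_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")]
  data.table::setnames(out, "duration", "duration_s")
  data.table::fwrite(out, path)
  if (!is.null(rejects) && nrow(rejects)) {
    data.table::fwrite(rejects, sub("\\.csv$", "_rejects.csv", path))
  }
  invisible(path)
}

#' Derive encounter order and the four interaction strata
#'
#' Within each learner x item x kind group, interactions are numbered
#' chronologically from 1 (`encounter_index`); ties on `start_time` are
#' broken by stable input order. The stratum is `initial_*` for
#' `encounter_index == 1` and `subsequent_*` otherwise. If
#' `encounter_index` is already present it is recomputed from time order,
#' making the operation idempotent.
#'
#' Exact duplicates of (learner, item, kind, start_time, duration) are
#' flagged as suspected duplicates in the `"duplicates"` attribute of the
#' result; they stay in the returned records (flagging, not dropping, is
#' the caller's contract).
#'
#' @param records A validated records table.
#' @return The records with `encounter_index` and `stratum` columns, sorted
#'   back to input order, with attribute `"duplicates"` holding suspected
#'   duplicate rows.
#' @export
derive_strata <- function(records) {
  dt <- data.table::copy(data.table::as.data.table(records))
  stopifnot(all(c("learner_id", "item_id", "kind", "start_time") %in% names(dt)))
  dt[, .row := .I]
  data.table::setorder(dt, learner_id, item_id, kind, start_time, .row)
  dt[, encounter_index := seq_len(.N), by = .(learner_id, item_id, kind)]
  dt[, stratum := data.table::fifelse(
    kind == "attempt",
    data.table::fifelse(encounter_index == 1L, "initial_attempt", "subsequent_attempt"),
    data.table::fifelse(encounter_index == 1L, "initial_feedback", "subsequent_feedback")
  )]
  dup <- duplicated(dt, by = c("learner_id", "item_id", "kind",
                               "start_time", "duration"))
  dups <- dt[dup]
  data.table::setorder(dt, .row)
  dt[, .row := NULL]
  dups[, .row := NULL]
  out <- dt[]
  data.table::setattr(out, "duplicates", dups[])
  out
}

#' Group interactions into module attempts
#'
#' Each learner x module pair becomes one module attempt: its interactions
#' sorted by start time, a completion flag, and (when completed) the
#' completion time, defined as the latest `start_time + duration`.
#'
#' @param records A validated records table. If it carries a `completed`
#'   column, that is used when `completions` is `NULL`.
#' @param completions Optional table with columns `learner_id`,
#'   `module_id`, `completed`; overrides any `completed` column. Marks for
#'   learner x module pairs with no interactions are returned as rejects.
#' @return A list with `attempts` (one row per learner x module:
#'   `n_interactions`, `completed`, `completion_time`, `first_start`) and
#'   `rejects` (orphan completion marks).
#' @export
group_module_attempts <- function(records, completions = NULL) {
  dt <- data.table::as.data.table(records)
  stopifnot(nrow(dt) > 0L)
  attempts <- dt[order(start_time),
                 .(n_interactions = .N,
                   first_start = start_time[1L],
                   completion_time = {
                     end <- start_time + duration
                     end[which.max(as.numeric(end))]
                   }),
                 by = .(learner_id, module_id)]
  rejects <- data.table::data.table(learner_id = character(),
                                    module_id = character(),
                                    reason = character())
  if (!is.null(completions)) {
    cm <- data.table::as.data.table(completions)
    stopifnot(all(c("learner_id", "module_id", "completed") %in% names(cm)))
    orphan <- cm[!attempts, on = c("learner_id", "module_id")]
    if (nrow(orphan)) {
      rejects <- orphan[, .(learner_id, module_id,
                            reason = "completion mark with no interactions")]
    }
    attempts[cm, on = c("learner_id", "module_id"),
             completed := i.completed]
    attempts[is.na(completed), completed := FALSE]
  } else if ("completed" %in% names(dt)) {
    comp <- dt[, .(completed = any(completed %in% TRUE)),
               by = .(learner_id, module_id)]
    attempts[comp, on = c("learner_id", "module_id"), completed := i.completed]
  } else {
    attempts[, completed := FALSE]
  }
  attempts[completed == FALSE, completion_time := as.POSIXct(NA)]
  list(attempts = attempts[], rejects = rejects[])
}
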