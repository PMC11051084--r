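# Synthetic event-log generator with ground-truth interruption labels.
#
# The generator states one "world": right-skewed lognormal base durations
# per stratum (anchored to published medians/means for attempts),
# multiplicative learner speed heterogeneity, mastery-style repeat
# encounters, sequential within-module timestamps with sub-timeout organic
# gaps, optional injected long (>= timeout) breaks, and additive injected
# pauses on a random subset of interactions. Every injected event is
# recorded in a truth table so recovery can be tested exactly.

.default_base_params <- function() {
  # medians 28 / 12 s and means 54.6 / 20.74 s for attempts pin
  # (meanlog, sdlog) = (ln median, sqrt(2 ln(mean/median))); feedback
  # strata have no published anchors and use round values.
  data.table::data.table(
    stratum = lapse_strata(),
    meanlog = c(log(28), log(12), log(20), log(10)),
    sdlog   = c(sqrt(2 * log(54.60 / 28)), sqrt(2 * log(20.74 / 12)), 1.0, 1.0)
  )
}

#' Configuration for the synthetic event-log generator
#'
#' Defaults describe a desk-scale cohort with the duration structure the
#' classifiers assume: lognormal per-stratum base durations (initial
#' attempts median ~28 s, subsequent ~12 s), lognormal learner speed
#' multipliers with median 1, a 2% interruption injection rate with
#' long-tailed additive pauses (median 600 s), and a 17.5% chance per
#' module attempt of one injected >= 30 min break.
#'
#' @param n_learners,n_modules,items_per_module Cohort dimensions.
#' @param encounters List controlling mastery-style repeats:
#'   `attempt_repeat_prob` (geometric continuation probability for extra
#'   attempts), `feedback_prob` (probability an item gets any feedback
#'   review), `feedback_repeat_prob` (continuation for extra reviews).
#' @param base_duration_params data.frame with columns `stratum`,
#'   `meanlog`, `sdlog`: lognormal parameters on the log-seconds scale.
#' @param speed_sigma sdlog of the per-learner lognormal speed multiplier
#'   (median 1); 0 disables speed heterogeneity.
#' @param interruption_prob Probability per interaction of an injected
#'   additive pause.
#' @param pause_sampler Function `n -> n positive pause seconds`; the
#'   default is lognormal with median 600 s. Long-tailed by design; no
#'   canonical family exists for true pause lengths so the sampler is
#'   fully configurable.
#' @param long_break_prob Probability per module attempt of one injected
#'   between-interaction break of at least `timeout_minutes`.
#' @param timeout_minutes Platform inactivity timeout (minutes).
#' @param calendar_start,calendar_end Inclusive `"YYYY-MM"` months over
#'   which module attempts are placed uniformly.
#' @param seed Integer master seed; drives per-learner substreams so the
#'   log is reproducible record-for-record.
#' @return A validated list of class `"eventlog_config"`.
#' @export
eventlog_config <- function(n_learners = 40L,
                            n_modules = 2L,
                            items_per_module = 12L,
                            encounters = list(attempt_repeat_prob = 0.40,
                                              feedback_prob = 0.45,
                                              feedback_repeat_prob = 0.25),
                            base_duration_params = .default_base_params(),
                            speed_sigma = 0.35,
                            interruption_prob = 0.02,
                            pause_sampler = function(n) rlnorm(n, log(600), 0.75),
                            long_break_prob = 0.175,
                            timeout_minutes = 30,
                            calendar_start = "2019-01",
                            calendar_end = "2022-12",
                            seed = 1L) {
  bp <- data.table::as.data.table(base_duration_params)
  stopifnot(
    n_learners >= 1L, n_modules >= 1L, items_per_module >= 1L,
    all(c("stratum", "meanlog", "sdlog") %in% names(bp)),
    setequal(bp$stratum, lapse_strata()),
    all(bp$sdlog >= 0),
    speed_sigma >= 0,
    interruption_prob >= 0, interruption_prob <= 1,
    long_break_prob >= 0, long_break_prob <= 1,
    timeout_minutes > 0,
    is.function(pause_sampler),
    vapply(encounters[c("attempt_repeat_prob", "feedback_prob",
                        "feedback_repeat_prob")],
           function(p) is.numeric(p) && p >= 0 && p < 1, logical(1))
  )
  t0 <- .month_start(calendar_start)
  t1 <- .month_end(calendar_end)
  stopifnot(!is.na(t0), !is.na(t1), t0 < t1)
  structure(list(
    n_learners = as.integer(n_learners),
    n_modules = as.integer(n_modules),
    items_per_module = as.integer(items_per_module),
    encounters = encounters,
    base_duration_params = bp,
    speed_sigma = speed_sigma,
    interruption_prob = interruption_prob,
    pause_sampler = pause_sampler,
    long_break_prob = long_break_prob,
    timeout_minutes = timeout_minutes,
    calendar_start = t0, calendar_end = t1,
    seed = as.integer(seed)
  ), class = "eventlog_config")
}

.month_start <- function(ym) {
  as.POSIXct(paste0(ym, "-01 00:00:00"), tz = "UTC")
}
.month_end <- function(ym) {
  s <- .month_start(ym)
  # first instant of the following month
  lt <- as.POSIXlt(s)
  lt$mon <- lt$mon + 1L
  as.POSIXct(lt)
}

# Events for one learner. Returns list(records, truth, session_truth).
.simulate_learner <- function(lid, cfg, speed_mult) {
  enc <- cfg$encounters
  bp <- cfg$base_duration_params
  span <- as.numeric(cfg$calendar_end) - as.numeric(cfg$calendar_start)
  recs <- vector("list", cfg$n_modules)
  sess <- vector("list", cfg$n_modules)
  for (m in seq_len(cfg$n_modules)) {
    mod_id <- sprintf("M%02d", m)
    items <- sprintf("%s_I%03d", mod_id, seq_len(cfg$items_per_module))
    n_att <- 1L + rgeom(length(items), 1 - enc$attempt_repeat_prob)
    has_fb <- runif(length(items)) < enc$feedback_prob
    n_fb <- ifelse(has_fb, 1L + rgeom(length(items), 1 - enc$feedback_repeat_prob), 0L)
    ev <- data.table::data.table(
      item_id = c(rep(items, n_att), rep(items, n_fb)),
      kind = rep(c("attempt", "feedback_review"), c(sum(n_att), sum(n_fb))),
      encounter_index = c(unlist(lapply(n_att, seq_len), use.names = FALSE),
                          unlist(lapply(n_fb, seq_len), use.names = FALSE))
    )
    # round-robin over encounter number emulates the platform cycling
    # through unmastered items; feedback follows attempts within a round
    data.table::setorder(ev, encounter_index, kind, item_id)
    ev[, stratum := data.table::fifelse(
      kind == "attempt",
      data.table::fifelse(encounter_index == 1L, "initial_attempt", "subsequent_attempt"),
      data.table::fifelse(encounter_index == 1L, "initial_feedback", "subsequent_feedback"))]
    ev[bp, on = "stratum", `:=`(meanlog = i.meanlog, sdlog = i.sdlog)]
    nev <- nrow(ev)
    base <- rlnorm(nev, ev$meanlog, ev$sdlog) * speed_mult
    injected <- runif(nev) < cfg$interruption_prob
    pause <- numeric(nev)
    if (any(injected)) pause[injected] <- cfg$pause_sampler(sum(injected))
    stopifnot(all(pause[injected] > 0))
    dur <- base + pause

    gaps <- pmin(rexp(nev - 1L, rate = 1 / 15),
                 cfg$timeout_minutes * 60 - 1)
    n_breaks <- 0L
    if (nev >= 2L && runif(1) < cfg$long_break_prob) {
      at <- sample.int(nev - 1L, 1L)
      gaps[at] <- cfg$timeout_minutes * 60 + rlnorm(1, log(1200), 0.5)
      n_breaks <- 1L
    }
    # integer seconds keep timestamps exact, so reconstructed gaps equal
    # injected gaps and the timeout boundary is never crossed by rounding
    dur <- pmax(round(dur), 1)
    t0 <- floor(as.numeric(cfg$calendar_start) +
                  runif(1) * max(span - 2 * 86400, 1))
    starts <- as.POSIXct(t0 + cumsum(c(0, head(dur, -1L) + ceiling(gaps)))[seq_len(nev)],
                         tz = "UTC", origin = "1970-01-01")

    ev[, `:=`(learner_id = lid, module_id = mod_id,
              start_time = starts, duration = dur,
              completed = TRUE, injected = injected,
              pause_s = data.table::fifelse(injected, pmax(round(pause, 2), 0.01), 0),
              meanlog = NULL, sdlog = NULL)]
    recs[[m]] <- ev
    sess[[m]] <- data.table::data.table(learner_id = lid, module_id = mod_id,
                                        session_truth = 1L + n_breaks)
  }
  list(records = data.table::rbindlist(recs),
       session_truth = data.table::rbindlist(sess))
}

#' Generate a ground-truth-labeled synthetic event log
#'
#' Durations are per-stratum lognormal base draws, scaled by the learner's
#' speed multiplier, plus an injected pause on interactions flagged as
#' interrupted. Timestamps run sequentially within each module attempt
#' with organic gaps below the timeout, except for injected long breaks.
#' The same seed reproduces the log byte-for-byte.
#'
#' @param config An [eventlog_config()].
#' @return A list of class `"labeled_eventlog"`:
#'   \describe{
#'     \item{records}{validated interaction records (with `stratum`,
#'       `encounter_index`, `completed`).}
#'     \item{truth}{per record: `injected` flag and `pause_s` seconds
#'       (0 iff not injected), in record order.}
#'     \item{session_truth}{per learner x module: true session count
#'       (1 + injected long breaks).}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
#' @examples
#' log <- simulate_eventlog(eventlog_config(n_learners = 5, seed = 42))
#' summarize_shape(log$records)
simulate_eventlog <- function(config) {
  stopifnot(inherits(config, "eventlog_config"))
  set.seed(config$seed)
  lids <- sprintf("L%05d", seq_len(config$n_learners))
  learner_seeds <- sample.int(.Machine$integer.max - 1L, config$n_learners)
  speed <- if (config$speed_sigma > 0) {
    rlnorm(config$n_learners, 0, config$speed_sigma)
  } else {
    rep(1, config$n_learners)
  }
  parts <- vector("list", config$n_learners)
  for (i in seq_len(config$n_learners)) {
    set.seed(learner_seeds[i])
    parts[[i]] <- .simulate_learner(lids[i], config, speed[i])
  }
  records <- data.table::rbindlist(lapply(parts, `[[`, "records"))
  truth <- records[, .(learner_id, item_id, module_id, kind,
                       encounter_index, injected, pause_s)]
  records[, `:=`(injected = NULL, pause_s = NULL)]
  data.table::setcolorder(records, c("learner_id", "item_id", "module_id",
                                     "kind", "encounter_index", "stratum",
                                     "start_time", "duration", "completed"))
  structure(list(
    records = records[],
    truth = truth[],
    session_truth = data.table::rbindlist(lapply(parts, `[[`, "session_truth")),
    config = config
  ), class = "labeled_eventlog")
}

#' @export
print.labeled_eventlog <- function(x, ...) {
  cat(sprintf(
    "<labeled_eventlog> %d records, %d learners, %d module attempts, %d injected pauses\n",
    nrow(x$records), length(unique(x$records$learner_id)),
    nrow(x$session_truth), sum(x$truth$injected)))
  invisible(x)
}

#' Per-stratum duration shape summary
#'
#' Used to verify that the generated (or observed) log shows the expected
#' right skew: for any lognormal base with positive log-scale spread, the
#' stratum mean exceeds its median.
#'
#' @param records A records table with `stratum` and `duration`.
#' @return data.table with per-stratum `n`, `median_dur`, `mean_dur`,
#'   `sd_dur`. Strata absent from the log are omitted with a warning.
#' @export
summarize_shape <- function(records) {
  dt <- data.table::as.data.table(records)
  stopifnot(nrow(dt) > 0L, all(c("stratum", "duration") %in% names(dt)))
  out <- dt[, .(n = .N, median_dur = median(duration),
                mean_dur = mean(duration), sd_dur = sd(duration)),
            by = stratum]
  missing_strata <- setdiff(lapse_strata(), out$stratum)
  if (length(missing_strata)) {
    warning("empty strata omitted: ", paste(missing_strata, collapse = ", "))
  }
  out[order(match(stratum, lapse_strata()))][]
}
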