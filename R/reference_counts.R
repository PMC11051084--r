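# Published aggregate counts shipped with the package.

#' Published period-level interruption counts
#'
#' Aggregate interruption/interaction counts per calendar period from a
#' published large-scale evaluation of a commercial adaptive
#' online-learning platform (2019-2022; about one billion interactions).
#' The raw event log behind these aggregates is proprietary, but the
#' period-level counts are public and suffice to reproduce the published
#' inference layer: chi-square tests of equal proportions and pairwise
#' Cohen's h.
#'
#' Five detection methods are covered: `mean_2sd` (per-item mean + 2 SD
#' thresholds), `speed_adjusted` (the same thresholds scaled by learner
#' speed factors), `speed_adjusted_restricted` (speed-adjusted, single
#' textbook sub-cohort), `modified_z` (MAD-based modified Z-scores on log
#' durations) and `long_interruption` (session-timeout counting; its
#' pre-COVID window starts October 2019 for data-quality reasons, and its
#' seasonality table has no usable April-May 2019 row).
#'
#' @param study Optional study number (1-5) to filter to.
#' @param comparison Optional `"hypothesis"` (pre/peak/post periods) or
#'   `"seasonality"` (April-May windows per year).
#' @return data.table with columns `study`, `method`, `comparison`,
#'   `period`, `interruptions`, `interactions`.
#' @export
#' @examples
#' t1 <- published_period_counts(study = 1, comparison = "hypothesis")
#' equal_proportions_test(t1$interruptions, t1$interactions)$chi2  # 107.16
published_period_counts <- function(study = NULL, comparison = NULL) {
  path <- system.file("extdata", "published_period_counts.csv",
                      package = "lapsepipe", mustWork = TRUE)
  dt <- data.table::fread(path)
  # filter with plain vectors: inside `[` the bare symbols would resolve
  # to the columns themselves
  sel_s <- if (is.null(study)) rep(TRUE, nrow(dt)) else dt[["study"]] %in% study
  sel_c <- if (is.null(comparison)) rep(TRUE, nrow(dt)) else dt[["comparison"]] %in% comparison
  dt[which(sel_s & sel_c)][]
}
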