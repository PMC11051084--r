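# Calendar-period aggregation and inference: rates by month and period,
# test of equal proportions, Cohen's h, SESOI verdicts, rate combination.

#' Calendar-period configuration
#'
#' Default periods reflect the US lockdown calendar: pre-COVID January
#' 2019 - February 2020, peak COVID April - May 2020, post-peak June
#' 2020 - December 2022, with March 2020 excluded as the transition month.
#' SESOI defaults: medium (0.5) for the pre-vs-peak contrast, small (0.3)
#' otherwise, on the Cohen's h scale.
#'
#' @param periods Named list of inclusive `c("YYYY-MM", "YYYY-MM")` month
#'   ranges; must not overlap after exclusions.
#' @param excluded Character vector of excluded `"YYYY-MM"` months.
#' @param sesoi Named numeric of SESOI values per comparison
#'   (`"p1_vs_p2"`), plus a `default` entry.
#' @return list of class `"period_config"`.
#' @export
period_config <- function(periods = list(pre_covid = c("2019-01", "2020-02"),
                                         peak_covid = c("2020-04", "2020-05"),
                                         post_peak = c("2020-06", "2022-12")),
                          excluded = "2020-03",
                          sesoi = c(pre_covid_vs_peak_covid = 0.5,
                                    default = 0.3)) {
  stopifnot(length(periods) >= 1L, !is.null(names(periods)),
            all(nzchar(names(periods))),
            all(vapply(periods, length, 0L) == 2L),
            is.numeric(sesoi), all(sesoi > 0), "default" %in% names(sesoi))
  months_of <- function(rng) {
    s <- seq(.month_start(rng[1]), .month_start(rng[2]), by = "month")
    format(s, "%Y-%m")
  }
  month_map <- lapply(periods, months_of)
  month_map <- lapply(month_map, setdiff, y = excluded)
  all_m <- unlist(month_map, use.names = FALSE)
  if (anyDuplicated(all_m)) {
    stop("periods overlap after exclusions: ",
         paste(unique(all_m[duplicated(all_m)]), collapse = ", "))
  }
  structure(list(periods = periods, excluded = excluded,
                 month_map = month_map, sesoi = sesoi),
            class = "period_config")
}

#' Seasonality-controlled period configuration
#'
#' One period per year over the same month window (default April-May),
#' for comparing a focal spring against the same season in other years.
#'
#' @param years Integer years.
#' @param months Integer months of the window (default `4:5`).
#' @param sesoi As in [period_config()].
#' @return A `"period_config"`.
#' @export
seasonal_config <- function(years = 2019:2022, months = 4:5,
                            sesoi = c(default = 0.3)) {
  rng <- lapply(years, function(y) sprintf("%d-%02d", y, range(months)))
  names(rng) <- sprintf("%s_%d",
                        paste(month.abb[range(months)], collapse = "_"), years)
  period_config(periods = rng, excluded = character(), sesoi = sesoi)
}

#' Assign calendar periods to timestamps
#'
#' Assignment is by UTC calendar month of the timestamp. Months listed as
#' excluded map to `"excluded"`; months in no period map to
#' `"out_of_scope"`.
#'
#' @param times POSIXct vector (or `"YYYY-MM"` strings).
#' @param config A [period_config()].
#' @return Character vector of period labels.
#' @export
assign_period <- function(times, config = period_config()) {
  stopifnot(inherits(config, "period_config"))
  m <- if (inherits(times, "POSIXt")) format(times, "%Y-%m", tz = "UTC")
       else as.character(times)
  out <- rep("out_of_scope", length(m))
  for (p in names(config$month_map)) out[m %in% config$month_map[[p]]] <- p
  out[m %in% config$excluded] <- "excluded"
  out
}

#' Monthly interruption rates and their unweighted mean
#'
#' The pooled rate per UTC calendar month is flagged/total in that month;
#' the unweighted mean is the plain average of monthly rates over months
#' with at least one classified interaction, so low-volume months count
#' as much as high-volume ones.
#'
#' @param records Records table.
#' @param classification A `"lapse_classification"` aligned with
#'   `records`; rejected records are excluded from both counts.
#' @return list `monthly` (data.table month, flagged, total, rate) and
#'   `mean_monthly_rate`.
#' @export
monthly_rates <- function(records, classification) {
  dt <- data.table::as.data.table(records)
  stopifnot(inherits(classification, "lapse_classification"),
            length(classification$flagged) == nrow(dt))
  work <- data.table::data.table(
    month = format(dt$start_time, "%Y-%m", tz = "UTC"),
    flagged = classification$flagged,
    rejected = classification$rejected)
  monthly <- work[rejected == FALSE,
                  .(flagged = sum(flagged), total = .N), by = month]
  monthly[, rate := flagged / total]
  data.table::setorder(monthly, month)
  list(monthly = monthly[], mean_monthly_rate = mean(monthly$rate))
}

#' Test of equal proportions across k groups
#'
#' Pearson chi-square on the k x 2 table of (flagged, not flagged) against
#' the pooled proportion, as `stats::prop.test()` computes it; df = k - 1.
#' The Yates continuity correction is applied only when `k == 2` and
#' `correct = TRUE`. If the pooled proportion is 0 or 1 the statistic is
#' returned as 0 with a warning (every group is then identical).
#'
#' @param flagged Integer vector of event counts per group.
#' @param total Integer vector of trial counts per group.
#' @param correct Continuity correction for the 2-group case.
#' @return list `chi2`, `df`, `p_value`, `proportions`.
#' @export
#' @examples
#' equal_proportions_test(c(30, 20), c(100, 100))$chi2  # 8/3
equal_proportions_test <- function(flagged, total, correct = FALSE) {
  stopifnot(length(flagged) == length(total), length(flagged) >= 2L,
            all(total > 0), all(flagged >= 0), all(flagged <= total))
  pooled <- sum(flagged) / sum(total)
  if (pooled == 0 || pooled == 1) {
    warning("pooled proportion is ", pooled, "; statistic is 0")
    return(list(chi2 = 0, df = length(flagged) - 1L, p_value = 1,
                proportions = flagged / total))
  }
  ht <- suppressWarnings(stats::prop.test(
    flagged, total, correct = correct && length(flagged) == 2L))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, proportions = flagged / total)
}

#' Cohen's h for two proportions
#'
#' h = 2 asin(sqrt(p1)) - 2 asin(sqrt(p2)); signed, antisymmetric, with
#' |h| <= pi. Roughly 0.2 is a small effect and 0.5 a medium one.
#'
#' @param p1,p2 Proportions in `[0, 1]` (vectorised).
#' @return Numeric h.
#' @export
#' @examples
#' cohens_h(0.25, 0.16)  # ~0.22416
cohens_h <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2))
}

#' Compare an effect size against the smallest effect size of interest
#'
#' @param h Cohen's h (sign ignored).
#' @param sesoi Positive SESOI on the h scale.
#' @return `"below_sesoi"` or `"at_or_above_sesoi"` (boundary counts as at
#'   or above).
#' @export
sesoi_verdict <- function(h, sesoi) {
  stopifnot(all(sesoi > 0))
  ifelse(abs(h) >= sesoi, "at_or_above_sesoi", "below_sesoi")
}

#' Combine within-session and long-interruption rates
#'
#' Within-session interruptions (duration outliers) and long interruptions
#' (session timeouts) are disjoint event classes over the same interaction
#' denominator, so the overall rate is their sum.
#'
#' @param within_rate,long_rate Rates sharing one denominator scope.
#' @return Combined rate.
#' @export
#' @examples
#' combine_rates(0.02855, 0.00351)  # 0.03206
combine_rates <- function(within_rate, long_rate) {
  stopifnot(all(within_rate >= 0), all(long_rate >= 0),
            all(within_rate + long_rate <= 1))
  within_rate + long_rate
}

#' Period-level interruption report
#'
#' Aggregates per-record flags into per-period counts and rates, runs the
#' test of equal proportions across periods, computes all pairwise Cohen's
#' h with SESOI verdicts, and attaches the monthly series.
#'
#' @param records Records table.
#' @param classification A `"lapse_classification"` aligned with `records`.
#' @param config A [period_config()].
#' @return list of class `"period_report"`: `periods` (data.table period,
#'   interruptions, interactions, rate), `test` (chi2, df, p_value),
#'   `pairwise` (data.table p1, p2, h, sesoi, verdict), `monthly`,
#'   `mean_monthly_rate`.
#' @export
period_report <- function(records, classification, config = period_config()) {
  dt <- data.table::as.data.table(records)
  stopifnot(inherits(classification, "lapse_classification"),
            length(classification$flagged) == nrow(dt))
  work <- data.table::data.table(
    period = assign_period(dt$start_time, config),
    flagged = classification$flagged,
    rejected = classification$rejected)
  per <- work[rejected == FALSE & period %in% names(config$periods),
              .(interruptions = sum(flagged), interactions = .N),
              by = period]
  per <- per[order(match(period, names(config$periods)))]
  per[, rate := interruptions / interactions]
  test <- if (nrow(per) >= 2L) {
    equal_proportions_test(per$interruptions, per$interactions)
  } else {
    NULL
  }
  pairs <- if (nrow(per) >= 2L) utils::combn(per$period, 2L) else NULL
  pairwise <- if (!is.null(pairs)) {
    data.table::rbindlist(apply(pairs, 2L, function(pp) {
      p1 <- per[period == pp[1]]
      p2 <- per[period == pp[2]]
      key <- paste0(pp[1], "_vs_", pp[2])
      ses <- if (key %in% names(config$sesoi)) config$sesoi[[key]]
             else config$sesoi[["default"]]
      h <- cohens_h(p1$rate, p2$rate)
      data.table::data.table(p1 = pp[1], p2 = pp[2], h = h, sesoi = ses,
                             verdict = sesoi_verdict(h, ses))
    }, simplify = FALSE))
  } else {
    NULL
  }
  mr <- monthly_rates(dt, classification)
  structure(list(periods = per[], test = test, pairwise = pairwise,
                 monthly = mr$monthly, mean_monthly_rate = mr$mean_monthly_rate,
                 method = classification$method),
            class = "period_report")
}

#' @export
print.period_report <- function(x, ...) {
  cat(sprintf("<period_report:%s>\n", x$method))
  print(x$periods)
  if (!is.null(x$test)) {
    cat(sprintf("equal proportions: chi2(%d) = %.4g, p = %.3g\n",
                x$test$df, x$test$chi2, x$test$p_value))
  }
  if (!is.null(x$pairwise)) print(x$pairwise)
  cat(sprintf("unweighted mean monthly rate: %.4g\n", x$mean_monthly_rate))
  invisible(x)
}
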