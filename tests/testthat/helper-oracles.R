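# Independent brute-force implementations used as oracles. These share no
# code path with the package: medians are computed from sorted vectors,
# group statistics with explicit loops, and the Pearson statistic from the
# textbook k x 2 expected-count formula.

o_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

o_mad <- function(v) o_median(abs(v - o_median(v)))

# mean + k*SD classifier, row-by-row
o_classify_mean_ksd <- function(rec, k = 2, min_n = 5L, factors = NULL) {
  flags <- logical(nrow(rec))
  rejected <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    grp <- rec$duration[rec$item_id == rec$item_id[i] &
                          rec$stratum == rec$stratum[i]]
    if (length(grp) < min_n) {
      rejected[i] <- TRUE
      next
    }
    thr <- mean(grp) + k * sd(grp)
    s <- 1
    if (!is.null(factors)) {
      hit <- factors$learner_id == rec$learner_id[i] &
        factors$stratum == rec$stratum[i]
      if (any(hit)) s <- factors$factor_s[which(hit)[1]]
    }
    flags[i] <- rec$duration[i] > s * thr
  }
  list(flagged = flags, rejected = rejected)
}

# modified Z-score classifier, row-by-row
o_classify_modz <- function(rec, factors = NULL, cutoff = 3.5, min_n = 5L) {
  sf <- function(i) {
    if (is.null(factors)) return(1)
    hit <- factors$learner_id == rec$learner_id[i] &
      factors$stratum == rec$stratum[i]
    if (any(hit)) factors$factor_s[which(hit)[1]] else 1
  }
  xs <- vapply(seq_len(nrow(rec)),
               function(i) log(rec$duration[i] / sf(i)), 0)
  flags <- logical(nrow(rec))
  rejected <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    idx <- which(rec$item_id == rec$item_id[i] & rec$stratum == rec$stratum[i])
    if (length(idx) < min_n) {
      rejected[i] <- TRUE
      next
    }
    med <- o_median(xs[idx])
    madv <- o_mad(xs[idx])
    if (madv == 0) next
    flags[i] <- 0.6745 * (xs[i] - med) / madv > cutoff
  }
  list(flagged = flags, rejected = rejected)
}

# session counter, attempt-by-attempt
o_session_counts <- function(rec, timeout_minutes = 30) {
  keys <- unique(rec[, c("learner_id", "module_id")])
  out <- integer(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- rec[rec$learner_id == keys$learner_id[i] &
                 rec$module_id == keys$module_id[i], ]
    sub <- sub[order(sub$start_time), ]
    cnt <- 1L
    if (nrow(sub) > 1L) {
      for (j in 2:nrow(sub)) {
        gap <- as.numeric(sub$start_time[j]) -
          (as.numeric(sub$start_time[j - 1L]) + sub$duration[j - 1L])
        if (gap >= timeout_minutes * 60) cnt <- cnt + 1L
      }
    }
    out[i] <- cnt
  }
  keys$session_count <- out
  keys
}

# textbook Pearson chi-square on the k x 2 table vs pooled expectation
o_pearson <- function(flagged, total) {
  p <- sum(flagged) / sum(total)
  obs <- rbind(flagged, total - flagged)
  exp_ <- rbind(total * p, total * (1 - p))
  sum((obs - exp_)^2 / exp_)
}
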