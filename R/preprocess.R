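#' Remove exact-duplicate participants
#'
#' Keeps the first record for each `participant_id`; later records with the
#' same id are treated as accidental duplicate submissions and dropped.
#'
#' @param participants participant table.
#' @return list with `participants` (deduplicated) and `log` (data.frame of
#'   removed ids with the rule name).
#' @export
remove_duplicates <- function(participants) {
  dup <- duplicated(participants$participant_id)
  log <- data.frame(participant_id = participants$participant_id[dup],
                    rule = rep("duplicate", sum(dup)),
                    statistic = rep(NA_real_, sum(dup)),
                    threshold = rep(NA_real_, sum(dup)),
                    stringsAsFactors = FALSE)
  list(participants = participants[!dup, , drop = FALSE], log = log)
}

#' Flag processing-time outliers
#'
#' Flags participants whose log total processing time lies more than `k_sd`
#' sample standard deviations from the sample mean of log time. Natural
#' logs are used (the base cancels out of the z-score). The mean and SD are
#' computed once, on the sample as given (run after duplicate removal); the
#' rule is a single pass, not iterative trimming.
#'
#' @param participants participant table with positive `total_time`.
#' @param k_sd flagging threshold in SD units (default 3).
#' @return list with `participants` (gains a logical `time_outlier` column)
#'   and `log` (flagged ids with their |z| statistic and threshold).
#' @export
flag_time_outliers <- function(participants, k_sd = 3) {
  stopifnot(all(participants$total_time > 0))
  lt <- log(participants$total_time)
  s <- sd(lt)
  if (!is.finite(s) || s == 0) {
    warning("zero variance in log processing time; no outliers flagged")
    z <- rep(0, length(lt))
  } else {
    z <- (lt - mean(lt)) / s
  }
  flag <- abs(z) > k_sd
  participants$time_outlier <- flag
  log <- data.frame(participant_id = participants$participant_id[flag],
                    rule = rep("time_outlier", sum(flag)),
                    statistic = abs(z)[flag],
                    threshold = rep(k_sd, sum(flag)),
                    stringsAsFactors = FALSE)
  list(participants = participants, log = log)
}

#' Aggregate trials to per-participant rejection proportions
#'
#' Computes, for each participant, the proportion of "harm unacceptable"
#' (reject) responses among congruent and among incongruent items — the two
#' observed proportions the processing-tree equations operate on.
#' Participants with missing trials (fewer than the expected per-congruency
#' count) are flagged, not dropped.
#'
#' @param trials trial table from [simulate_trials()] (or equivalent).
#' @param n_per_congruency expected items per congruency (default 10).
#' @return data.frame with `participant_id`, `n_cong`, `n_incong`,
#'   `p_unacc_cong`, `p_unacc_incong`, `incomplete`.
#' @export
aggregate_trials <- function(trials, n_per_congruency = 10) {
  stopifnot(all(c("participant_id", "congruency", "response")
                %in% names(trials)))
  rej <- trials$response == "reject_harm"
  ids <- unique(trials$participant_id)
  f <- factor(trials$participant_id, levels = ids)
  cong <- trials$congruency == "congruent"
  n_c <- tapply(cong, f, sum)
  n_i <- tapply(!cong, f, sum)
  r_c <- tapply(rej & cong, f, sum)
  r_i <- tapply(rej & !cong, f, sum)
  out <- data.frame(participant_id = ids,
                    n_cong = as.integer(n_c),
                    n_incong = as.integer(n_i),
                    p_unacc_cong = as.numeric(r_c / n_c),
                    p_unacc_incong = as.numeric(r_i / n_i),
                    stringsAsFactors = FALSE)
  out$incomplete <- out$n_cong != n_per_congruency |
    out$n_incong != n_per_congruency
  rownames(out) <- NULL
  out
}

#' Run the exclusion pipeline
#'
#' Applies the fixed exclusion order — duplicates, then log-time outliers,
#' then (optionally) a minimum-total-time compliance rule — and returns the
#' retained participants plus a cumulative exclusion log. Rerunning on its
#' own output is idempotent.
#'
#' @param participants participant table.
#' @param k_sd SD threshold for the log-time rule.
#' @param min_total_time optional minimum total time in seconds (a
#'   compliance rule for participants answering implausibly fast); `NULL`
#'   disables it.
#' @return list with `participants` (retained rows only) and `log`.
#' @export
apply_exclusions <- function(participants, k_sd = 3, min_total_time = NULL) {
  d <- remove_duplicates(participants)
  o <- flag_time_outliers(d$participants, k_sd = k_sd)
  keep <- !o$participants$time_outlier
  log <- rbind(d$log, o$log)
  retained <- o$participants[keep, , drop = FALSE]
  if (!is.null(min_total_time)) {
    fast <- retained$total_time < min_total_time
    log <- rbind(log, data.frame(
      participant_id = retained$participant_id[fast],
      rule = rep("min_total_time", sum(fast)),
      statistic = retained$total_time[fast],
      threshold = rep(min_total_time, sum(fast)),
      stringsAsFactors = FALSE))
    retained <- retained[!fast, , drop = FALSE]
  }
  retained$time_outlier <- NULL
  rownames(retained) <- NULL
  list(participants = retained, log = log)
}
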