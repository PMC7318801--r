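#' Estimate the process-dissociation parameters for each participant
#'
#' The processing tree implies, per participant,
#' `p(reject | congruent) = U + (1 - U) * D` and
#' `p(reject | incongruent) = (1 - U) * D`, which invert to
#' `U = p_cong - p_incong` and `D = p_incong / (1 - U)`. Estimation applies
#' the two conditioning steps needed for weighted logistic regression, in
#' this order: negative raw values are clamped to 0 first (a probability
#' cannot be negative; clamping moves an errorful estimate to the nearest
#' meaningful value), then values are rounded onto the 1/weight grid so that
#' weight x value is an integer (see [round_to_grid()]). The reported D uses
#' the clamped U in its denominator; the fully raw ratio is kept in `D_raw`.
#' When `U_raw = 1` the D denominator vanishes and D is undefined — flagged,
#' never silently zeroed.
#'
#' @param agg per-participant aggregate from [aggregate_trials()].
#' @param weight grid weight for regression conditioning (default 20, the
#'   total number of dilemmas the proportions are based on).
#' @return data.frame with `participant_id`, `U_raw`, `D_raw`, `U`, `D`,
#'   `grid_U`, `grid_D`, `clamped`, `d_undefined`, `weight`.
#' @export
#' @examples
#' agg <- data.frame(participant_id = "p1",
#'                   p_unacc_cong = 0.86, p_unacc_incong = 0.45)
#' estimate_pd(agg)  # U = 0.41, D = 0.45/0.59
estimate_pd <- function(agg, weight = 20) {
  stopifnot(all(c("p_unacc_cong", "p_unacc_incong") %in% names(agg)),
            all(agg$p_unacc_cong >= 0 & agg$p_unacc_cong <= 1),
            all(agg$p_unacc_incong >= 0 & agg$p_unacc_incong <= 1))
  U_raw <- agg$p_unacc_cong - agg$p_unacc_incong
  D_raw <- ifelse(U_raw < 1, agg$p_unacc_incong / (1 - U_raw), NA_real_)
  U <- pmin(pmax(U_raw, 0), 1)
  d_undefined <- U >= 1
  D <- ifelse(d_undefined, NA_real_, agg$p_unacc_incong / (1 - U))
  data.frame(
    participant_id = agg$participant_id,
    U_raw = U_raw, D_raw = D_raw,
    U = U, D = D,
    grid_U = round_to_grid(U, weight),
    grid_D = ifelse(d_undefined, NA_real_, round_to_grid(D, weight)),
    clamped = U_raw < 0,
    d_undefined = d_undefined,
    weight = as.integer(weight),
    stringsAsFactors = FALSE)
}

#' Round values onto the 1/weight grid
#'
#' Rounds to the nearest multiple of `1/weight` so that `weight * value` is
#' an integer — required for entering proportions as (successes, failures)
#' pairs in weighted logit models. Exact ties round away from zero (e.g.
#' 0.425 with weight 20 gives 0.45). Clamping must be applied before
#' rounding; this function only rounds.
#'
#' @param x numeric vector in `[0, 1]` (NAs pass through).
#' @param weight positive integer grid weight.
#' @return numeric vector of grid values.
#' @export
#' @examples
#' round_to_grid(c(0.42, 0.44), 20)  # 0.40, 0.45
round_to_grid <- function(x, weight) {
  if (weight < 1 || weight != round(weight)) {
    stop("weight must be a positive integer")
  }
  # round() in R goes half-to-even; half-away-from-zero is wanted here.
  # The pre-round to 9 digits absorbs binary representation error in
  # literals like 0.425 * 20.
  scaled <- round(x * weight, 9)
  sign(scaled) * floor(abs(scaled) + 0.5) / weight
}

#' Conventional one-dimensional measure of moral inclinations
#'
#' The proportion of harm-accepting ("utilitarian") responses among the
#' incongruent dilemmas only. High scores indicate predominance of
#' utilitarian, low scores of deontological inclinations; the PD parameters
#' decompose this single dimension. Its regression weight is the number of
#' incongruent items (10).
#'
#' @param trials trial table.
#' @param n_incong expected incongruent items per participant (default 10).
#' @return data.frame with `participant_id`, `conventional` (in `[0, 1]`),
#'   `weight`, `incomplete`.
#' @export
conventional_measure <- function(trials, n_incong = 10) {
  inc <- trials[trials$congruency == "incongruent", , drop = FALSE]
  ids <- unique(trials$participant_id)
  f <- factor(inc$participant_id, levels = ids)
  n <- tapply(rep(1, nrow(inc)), f, sum)
  n[is.na(n)] <- 0
  acc <- tapply(inc$response == "accept_harm", f, sum)
  acc[is.na(acc)] <- 0
  out <- data.frame(participant_id = ids,
                    conventional = as.numeric(acc) / pmax(as.numeric(n), 1),
                    weight = as.integer(n_incong),
                    incomplete = as.numeric(n) != n_incong,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pooled group-level PD estimate
#'
#' Applies the processing-tree equations to proportions pooled over all
#' trials of a group, rather than per participant. Provided for descriptive
#' use; the analyses in this package are individual-level.
#'
#' @param trials trial table for one group.
#' @return one-row data.frame with pooled `p_unacc_cong`, `p_unacc_incong`,
#'   `U`, `D`.
#' @export
pd_group_estimate <- function(trials) {
  rej <- trials$response == "reject_harm"
  cong <- trials$congruency == "congruent"
  p_c <- mean(rej[cong])
  p_i <- mean(rej[!cong])
  U <- p_c - p_i
  data.frame(p_unacc_cong = p_c, p_unacc_incong = p_i,
             U = max(U, 0),
             D = if (U < 1) p_i / (1 - max(U, 0)) else NA_real_)
}

#' Per-condition summary of the PD parameters
#'
#' Builds the descriptive table of a PD experiment: per condition cell, the
#' mean and SD of D, U and the conventional measure, and the Pearson
#' correlation between the participants' D and U values with its two-sided
#' p-value. Cells report the effective n entering the D summaries
#' (participants with undefined D are excluded from those).
#'
#' @param estimates output of [estimate_pd()].
#' @param participants participant table carrying the condition factors
#'   (`instrumentality`, `personal_force`).
#' @param scores optional output of [conventional_measure()].
#' @return data.frame with one row per condition cell.
#' @export
cell_summaries <- function(estimates, participants, scores = NULL) {
  d <- merge(estimates,
             participants[, c("participant_id", "instrumentality",
                              "personal_force")],
             by = "participant_id")
  if (!is.null(scores)) {
    d <- merge(d, scores[, c("participant_id", "conventional")],
               by = "participant_id", all.x = TRUE)
  }
  cells <- unique(d[, c("instrumentality", "personal_force")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- d[d$instrumentality == cells$instrumentality[i] &
             d$personal_force == cells$personal_force[i], , drop = FALSE]
    stopifnot(nrow(sub) >= 2)
    ok <- !sub$d_undefined
    ct <- pd_pearson(sub$D[ok], sub$U[ok])
    data.frame(
      instrumentality = cells$instrumentality[i],
      personal_force = cells$personal_force[i],
      n = nrow(sub), n_d_defined = sum(ok),
      D_mean = mean(sub$D[ok]), D_sd = sd(sub$D[ok]),
      U_mean = mean(sub$U), U_sd = sd(sub$U),
      conventional_mean = if (is.null(scores)) NA_real_
                          else mean(sub$conventional, na.rm = TRUE),
      conventional_sd = if (is.null(scores)) NA_real_
                        else sd(sub$conventional, na.rm = TRUE),
      r_DU = ct$r, r_DU_p = ct$p,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
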