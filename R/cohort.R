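#' Published cell-level targets for the PD parameters
#'
#' Per-condition means (and SDs, as attributes of the columns' names kept in
#' `D_sd`/`U_sd`) of the deontology (D) and utilitarianism (U) parameters
#' reported for the three experiments these tools emulate. Experiment 1
#' manipulated instrumentality only (personal dilemmas); Experiments 2 and 3
#' crossed instrumentality with personal force.
#'
#' @param experiment 1, 2 or 3.
#' @return data.frame with one row per condition cell: `instrumentality`,
#'   `personal_force`, `D_mean`, `D_sd`, `U_mean`, `U_sd`, `n`.
#' @export
pd_cell_targets <- function(experiment = 3) {
  stopifnot(experiment %in% 1:3)
  if (experiment == 1) {
    return(data.frame(
      instrumentality = c("side_effect", "means"),
      personal_force = "personal",
      D_mean = c(0.62, 0.80), D_sd = c(0.27, 0.26),
      U_mean = c(0.55, 0.28), U_sd = c(0.20, 0.22),
      n = c(31, 30),
      stringsAsFactors = FALSE))
  }
  cells <- data.frame(
    instrumentality = c("side_effect", "means", "side_effect", "means"),
    personal_force = c("impersonal", "impersonal", "personal", "personal"),
    stringsAsFactors = FALSE)
  if (experiment == 2) {
    cells$D_mean <- c(0.47, 0.71, 0.67, 0.79)
    cells$D_sd <- c(0.28, 0.22, 0.25, 0.22)
    cells$U_mean <- c(0.50, 0.23, 0.35, 0.28)
    cells$U_sd <- c(0.21, 0.14, 0.25, 0.19)
    cells$n <- 22
  } else {
    cells$D_mean <- c(0.42, 0.56, 0.55, 0.76)
    cells$D_sd <- c(0.28, 0.27, 0.30, 0.22)
    cells$U_mean <- c(0.50, 0.25, 0.42, 0.25)
    cells$U_sd <- c(0.24, 0.21, 0.25, 0.20)
    cells$n <- 75
  }
  cells
}

#' Specify a synthetic cohort
#'
#' Describes the population the generator draws from: per-condition target
#' means for the latent D and U inclinations, between-participant
#' heterogeneity on the logit scale, sex composition, a lognormal model of
#' total processing time, and rates (or exact counts) of quality-control
#' artifacts to inject.
#'
#' Individual inclinations are drawn logit-normally: the cell's location on
#' the logit scale is solved numerically so that the population mean of the
#' back-transformed draws equals the target cell mean exactly.
#'
#' @param cells data.frame like [pd_cell_targets()]; columns
#'   `instrumentality`, `personal_force`, `D_mean`, `U_mean` and optionally
#'   `n` (per-cell sample size, overridden by `n_per_cell` if given).
#' @param n_per_cell participants per condition cell (NULL = take from
#'   `cells$n`).
#' @param sd_logit between-participant SD of each inclination on the logit
#'   scale (default 1.3, which back-transforms to probability-scale SDs of
#'   roughly 0.2-0.3 across the plausible mean range).
#' @param latent_cor correlation between the D and U logits within a
#'   participant (default 0: independent inclinations).
#' @param sex_prop named proportions for `female`, `male`, `other`.
#' @param time_meanlog,time_sdlog lognormal parameters of total processing
#'   time in seconds.
#' @param duplicate_rate,outlier_rate expected fraction of participants to
#'   duplicate / to give an extreme processing time (see
#'   [inject_artifacts()]).
#' @param n_duplicates,n_outliers exact artifact counts; when non-NULL they
#'   take precedence over the rates.
#' @param seed integer root seed for the whole cohort.
#' @return object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(cells = pd_cell_targets(3), n_per_cell = NULL,
                        sd_logit = 1.3, latent_cor = 0,
                        sex_prop = c(female = 0.76, male = 0.23, other = 0.01),
                        time_meanlog = log(1200), time_sdlog = 0.5,
                        duplicate_rate = 0, outlier_rate = 0,
                        n_duplicates = NULL, n_outliers = NULL,
                        seed = 1L) {
  stopifnot(is.data.frame(cells),
            all(c("instrumentality", "personal_force",
                  "D_mean", "U_mean") %in% names(cells)))
  if (!is.null(n_per_cell)) cells$n <- n_per_cell
  if (is.null(cells$n)) stop("per-cell n must be given via cells$n or n_per_cell")
  stopifnot(all(cells$n >= 1),
            all(cells$D_mean >= 0 & cells$D_mean <= 1),
            all(cells$U_mean >= 0 & cells$U_mean <= 1),
            sd_logit >= 0, abs(latent_cor) <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1,
            time_sdlog >= 0)
  if (sd_logit > 0 &&
      any(cells$D_mean %in% c(0, 1) | cells$U_mean %in% c(0, 1))) {
    stop("cell means of 0 or 1 are unreachable with nonzero logit dispersion")
  }
  sex_prop <- sex_prop / sum(sex_prop)
  structure(list(cells = cells, sd_logit = sd_logit,
                 latent_cor = latent_cor, sex_prop = sex_prop,
                 time_meanlog = time_meanlog, time_sdlog = time_sdlog,
                 duplicate_rate = duplicate_rate,
                 outlier_rate = outlier_rate,
                 n_duplicates = n_duplicates, n_outliers = n_outliers,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# location mu of a logit-normal(mu, sigma) with a given mean
.logitnorm_location <- function(target_mean, sigma) {
  if (sigma == 0) return(qlogis(target_mean))
  f <- function(mu) {
    integrate(function(z) plogis(mu + sigma * z) * dnorm(z),
              -8, 8, rel.tol = 1e-10)$value - target_mean
  }
  uniroot(f, c(-20, 20), tol = 1e-10)$root
}

#' Sample the latent participants of a cohort
#'
#' Draws per-participant latent inclinations (`D_true`, `U_true`) around the
#' spec's cell means, a sex covariate, and a lognormal total processing
#' time. Reproducible from the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with `participant_id`, `instrumentality`,
#'   `personal_force`, `sex`, `D_true`, `U_true`, `total_time`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  cells <- spec$cells
  sig <- spec$sd_logit
  rho <- spec$latent_cor
  out <- lapply(seq_len(nrow(cells)), function(i) {
    n <- cells$n[i]
    mu_d <- .logitnorm_location(cells$D_mean[i], sig)
    mu_u <- .logitnorm_location(cells$U_mean[i], sig)
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    data.frame(
      instrumentality = cells$instrumentality[i],
      personal_force = cells$personal_force[i],
      sex = sample(names(spec$sex_prop), n, replace = TRUE,
                   prob = spec$sex_prop),
      D_true = plogis(mu_d + sig * z1),
      U_true = plogis(mu_u + sig * z2),
      total_time = rlnorm(n, spec$time_meanlog, spec$time_sdlog),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- cbind(participant_id = sprintf("P%04d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate trial-level responses from the processing tree
#'
#' Each trial's response is Bernoulli under the PD processing tree: the
#' probability of judging the harm unacceptable is `U + (1 - U) * D` on
#' congruent items and `(1 - U) * D` on incongruent items. Items are
#' presented in one of a small set of frozen semi-random orders per
#' condition (cycled over participants), mirroring standard practice.
#'
#' @param cohort data.frame from [sample_cohort()].
#' @param battery battery covering every condition present in the cohort
#'   (default: the full 2 x 2 battery).
#' @param seed integer seed for the response draws and order generation.
#' @param n_orders frozen orders per condition (default 5).
#' @return data.frame of trial records: `participant_id`, `item_id`,
#'   `congruency`, `instrumentality`, `personal_force`, `response`
#'   (`"accept_harm"`/`"reject_harm"`), `position`.
#' @export
simulate_trials <- function(cohort, battery = full_battery(), seed = 1L,
                            n_orders = 5) {
  stopifnot(all(c("participant_id", "D_true", "U_true") %in% names(cohort)))
  conds <- unique(cohort[, c("instrumentality", "personal_force")])
  orders <- list()
  for (i in seq_len(nrow(conds))) {
    key <- paste(conds$instrumentality[i], conds$personal_force[i], sep = ".")
    sub <- battery[battery$instrumentality == conds$instrumentality[i] &
                   battery$personal_force == conds$personal_force[i], ,
                   drop = FALSE]
    if (nrow(sub) == 0) stop("battery lacks condition ", key)
    orders[[key]] <- freeze_orders(sub, seed = as.integer(seed) + 1000L * i,
                                   n_orders = n_orders)
  }
  set.seed(as.integer(seed))
  res <- vector("list", nrow(cohort))
  for (j in seq_len(nrow(cohort))) {
    key <- paste(cohort$instrumentality[j], cohort$personal_force[j],
                 sep = ".")
    ord <- orders[[key]][[((j - 1) %% n_orders) + 1]]
    sub <- battery[match(ord$item_id, battery$item_id), , drop = FALSE]
    p_rej <- ifelse(sub$congruency == "congruent",
                    cohort$U_true[j] + (1 - cohort$U_true[j]) * cohort$D_true[j],
                    (1 - cohort$U_true[j]) * cohort$D_true[j])
    rej <- rbinom(nrow(sub), 1, p_rej) == 1
    res[[j]] <- data.frame(
      participant_id = cohort$participant_id[j],
      item_id = sub$item_id,
      congruency = sub$congruency,
      instrumentality = sub$instrumentality,
      personal_force = sub$personal_force,
      response = ifelse(rej, "reject_harm", "accept_harm"),
      position = seq_len(nrow(sub)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Inject quality-control artifacts into a simulated dataset
#'
#' Adds exact-duplicate participants (same id and payload, appended again)
#' and replaces some participants' total processing times with extreme
#' values (alternately a few seconds and several hours), as challenges for
#' the duplicate-removal and log-time outlier rules. Ground-truth labels are
#' retained in `injected_duplicate` / `injected_outlier` columns.
#'
#' @param participants participant table from [sample_cohort()].
#' @param trials matching trial table from [simulate_trials()] (optional;
#'   duplicated participants get their trial rows duplicated too).
#' @param spec the [cohort_spec()]; its `duplicate_rate`/`outlier_rate` (or
#'   exact `n_duplicates`/`n_outliers`) and seed are used.
#' @return list with elements `participants`, `trials`.
#' @export
inject_artifacts <- function(participants, trials = NULL, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed + 77L)
  n <- nrow(participants)
  n_dup <- if (!is.null(spec$n_duplicates)) spec$n_duplicates
           else rbinom(1, n, spec$duplicate_rate)
  n_out <- if (!is.null(spec$n_outliers)) spec$n_outliers
           else rbinom(1, n, spec$outlier_rate)
  stopifnot(n_dup <= n, n_out <= n)

  participants$injected_duplicate <- FALSE
  participants$injected_outlier <- FALSE

  if (n_out > 0) {
    idx <- sample(n, n_out)
    fast <- seq_along(idx) %% 2 == 1
    participants$total_time[idx[fast]] <- runif(sum(fast), 5, 14)
    participants$total_time[idx[!fast]] <- runif(sum(!fast), 4, 10) * 3600
    participants$injected_outlier[idx] <- TRUE
  }
  if (n_dup > 0) {
    idx <- sample(n, n_dup)
    dup <- participants[idx, , drop = FALSE]
    dup$injected_duplicate <- TRUE
    participants <- rbind(participants, dup)
    if (!is.null(trials)) {
      extra <- trials[trials$participant_id %in% dup$participant_id, ,
                      drop = FALSE]
      trials <- rbind(trials, extra)
    }
  }
  rownames(participants) <- NULL
  list(participants = participants, trials = trials)
}
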