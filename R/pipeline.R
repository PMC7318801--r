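#' Analysis configuration
#'
#' A validated, fully serializable description of one pipeline run. A run
#' is reproducible from the config alone: every source of randomness is
#' derived from its single `seed`.
#'
#' @param seed root seed (integer).
#' @param experiment 1, 2 or 3: which published design's cell targets the
#'   simulated cohort emulates (see [pd_cell_targets()]); ignored when
#'   `cells` is given.
#' @param cells optional custom cell-target data.frame.
#' @param n_per_cell participants per condition cell (NULL = the design's
#'   published cell sizes).
#' @param sd_logit,latent_cor cohort heterogeneity, see [cohort_spec()].
#' @param n_duplicates,n_outliers artifacts to inject (counts; 0 = none).
#' @param k_sd log-time outlier threshold in SD units.
#' @param min_total_time optional compliance floor on total time (seconds).
#' @param weight grid weight for the PD parameters (20).
#' @param overdispersion_threshold dispersion above which quasibinomial
#'   follow-ups are reported as the primary ones.
#' @param include_sex whether to fit the sex-moderation model.
#' @param correlation_tail `"two_sided"` or `"one_sided"` for the Fisher-z
#'   comparisons.
#' @param power list of arguments for [rm_interaction_sensitivity()], or
#'   NULL to skip the sensitivity analysis.
#' @return object of class `pd_config` (a list).
#' @export
pd_config <- function(seed = 1L, experiment = 3, cells = NULL,
                      n_per_cell = NULL, sd_logit = 1.3, latent_cor = 0,
                      n_duplicates = 0, n_outliers = 0, k_sd = 3,
                      min_total_time = NULL, weight = 20,
                      overdispersion_threshold = 1.5,
                      include_sex = FALSE,
                      correlation_tail = "two_sided",
                      power = list(n_total = 60, n_groups = 2,
                                   n_measures = 2, rho = -0.45,
                                   alpha = 0.05, target_power = 0.80)) {
  if (is.null(cells)) cells <- pd_cell_targets(experiment)
  cfg <- list(seed = as.integer(seed), cells = cells,
              n_per_cell = n_per_cell, sd_logit = sd_logit,
              latent_cor = latent_cor,
              n_duplicates = as.integer(n_duplicates),
              n_outliers = as.integer(n_outliers),
              k_sd = k_sd, min_total_time = min_total_time,
              weight = as.integer(weight),
              overdispersion_threshold = overdispersion_threshold,
              include_sex = isTRUE(include_sex),
              correlation_tail = match.arg(correlation_tail,
                                           c("two_sided", "one_sided")),
              power = power)
  structure(cfg, class = "pd_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys correspond to the arguments of [pd_config()]; the `cells`
#' key, if present, must be a list of per-cell records.
#'
#' @param path YAML file path.
#' @return a `pd_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cells)) {
    raw$cells <- do.call(rbind, lapply(raw$cells, as.data.frame))
  }
  do.call(pd_config, raw)
}

#' Congruent vs incongruent acceptance-rate contrast
#'
#' Models each participant's harm-acceptance proportion in the congruent
#' and incongruent items (weight = items per congruency) with a logit
#' mixed model having congruency as the repeated-measures factor and a
#' random intercept per participant, and tests the congruency effect with
#' a likelihood ratio test.
#'
#' @param agg aggregates from [aggregate_trials()].
#' @param n_per_congruency items per congruency (weight, default 10).
#' @return list with `acceptance_cong`, `acceptance_incong` (grand means),
#'   their SDs, the fitted `pd_fit`, the `lrt` row and the congruency odds
#'   ratio.
#' @export
congruency_contrast <- function(agg, n_per_congruency = 10) {
  acc_c <- 1 - agg$p_unacc_cong
  acc_i <- 1 - agg$p_unacc_incong
  long <- data.frame(
    participant_id = factor(rep(agg$participant_id, 2)),
    congruency = factor(rep(c("congruent", "incongruent"),
                            each = nrow(agg)),
                        levels = c("congruent", "incongruent")),
    successes = as.integer(round(c(acc_c, acc_i) * n_per_congruency)))
  long$failures <- n_per_congruency - long$successes
  full <- fit_mixed_logit(long, fixed = ~ congruency,
                          random = "(1 | participant_id)")
  null <- fit_mixed_logit(long, fixed = ~ 1,
                          random = "(1 | participant_id)")
  test <- lrt(full, null)
  or <- full$coefficients$or[full$coefficients$term == "congruencyincongruent"]
  list(acceptance_cong = mean(acc_c), acceptance_cong_sd = sd(acc_c),
       acceptance_incong = mean(acc_i), acceptance_incong_sd = sd(acc_i),
       fit = full, lrt = test, odds_ratio = or)
}

# fixed-effect formulas for the designs with one or two between factors
.design_terms <- function(two_factor) {
  if (two_factor) {
    list(full = ~ parameter * instrumentality * personal_force,
         between = ~ instrumentality * personal_force)
  } else {
    list(full = ~ parameter * instrumentality,
         between = ~ instrumentality)
  }
}

# drop one term from a one-sided formula
.drop_term <- function(fml, term) {
  as.formula(paste("~", paste(deparse(fml[[2]]), collapse = " "), "-", term))
}

#' Run the full analysis pipeline
#'
#' Simulate a cohort, inject and then screen out quality-control
#' artifacts, aggregate, estimate the PD parameters, and run the full
#' analysis battery: the congruency acceptance contrast, the weighted logit
#' mixed model with LRTs for the parameter-type interactions, quasibinomial
#' follow-up GLMs per parameter, the conventional-measure logit analysis,
#' the per-cell descriptive table with D-U correlations, all pairwise
#' Fisher-z correlation comparisons, and the sensitivity power analysis.
#' Identical config (including seed) gives identical output.
#'
#' @param config a [pd_config()].
#' @param output_dir optional directory; when given, CSV tables, the
#'   exclusion log and a JSON bundle of every computed statistic are
#'   written there.
#' @return list (invisibly also written as JSON when `output_dir` is set)
#'   with elements `data`, `exclusions`, `cell_summaries`,
#'   `congruency_contrast`, `mixed_logit`, `lrt_tests`, `followup_glms`,
#'   `conventional_analysis`, `correlations`, `power`, `config_digest`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "pd_config"))
  spec <- cohort_spec(cells = config$cells, n_per_cell = config$n_per_cell,
                      sd_logit = config$sd_logit,
                      latent_cor = config$latent_cor,
                      n_duplicates = if (config$n_duplicates > 0)
                        config$n_duplicates else NULL,
                      n_outliers = if (config$n_outliers > 0)
                        config$n_outliers else NULL,
                      seed = config$seed)
  cohort <- sample_cohort(spec)
  two_factor <- length(unique(cohort$personal_force)) > 1
  battery <- full_battery(
    instrumentality = unique(cohort$instrumentality),
    personal_force = unique(cohort$personal_force))
  trials <- simulate_trials(cohort, battery, seed = config$seed + 1L)
  if (config$n_duplicates > 0 || config$n_outliers > 0) {
    inj <- inject_artifacts(cohort, trials, spec)
    cohort <- inj$participants
    trials <- inj$trials
  }

  excl <- apply_exclusions(cohort, k_sd = config$k_sd,
                           min_total_time = config$min_total_time)
  participants <- excl$participants
  trials <- trials[trials$participant_id %in% participants$participant_id, ,
                   drop = FALSE]
  trials <- trials[!duplicated(paste(trials$participant_id,
                                     trials$item_id)), , drop = FALSE]

  agg <- aggregate_trials(trials)
  est <- estimate_pd(agg, weight = config$weight)
  conv <- conventional_measure(trials)
  cells_tab <- cell_summaries(est, participants, conv)
  contrast <- congruency_contrast(agg)

  long <- pd_long(est, participants)
  terms <- .design_terms(two_factor)
  fit_full <- fit_mixed_logit(long, fixed = terms$full)
  # each interaction is tested against the largest model in which its
  # removal is a one-parameter restriction (dropping a two-way while the
  # three-way stays is not a nested comparison under marginality coding)
  if (two_factor) {
    fml_two <- ~ (parameter + instrumentality + personal_force)^2
    fit_two <- fit_mixed_logit(long, fixed = fml_two)
    lrts <- list(
      parameter_x_instrumentality = lrt(
        fit_two, fit_mixed_logit(long, fixed = .drop_term(
          fml_two, "parameter:instrumentality"))),
      parameter_x_personal_force = lrt(
        fit_two, fit_mixed_logit(long, fixed = .drop_term(
          fml_two, "parameter:personal_force"))),
      three_way = lrt(fit_full, fit_two))
  } else {
    lrts <- list(
      parameter_x_instrumentality = lrt(
        fit_full, fit_mixed_logit(long, fixed = .drop_term(
          terms$full, "parameter:instrumentality"))))
  }

  sex_analysis <- NULL
  if (config$include_sex && "sex" %in% names(long) &&
      length(unique(long$sex)) > 1) {
    fml_sex <- as.formula(paste("~", paste(deparse(terms$full[[2]]), collapse = " "),
                                "+ sex + sex:parameter"))
    fit_sex <- fit_mixed_logit(long, fixed = fml_sex)
    sex_analysis <- list(
      fit = fit_sex,
      lrt_sex_x_parameter = lrt(
        fit_sex, fit_mixed_logit(long, fixed = as.formula(
          paste("~", paste(deparse(terms$full[[2]]), collapse = " "), "+ sex")))))
  }

  glm_data <- merge(est, participants, by = "participant_id")
  glm_data$instrumentality <- factor(glm_data$instrumentality,
                                     levels = c("side_effect", "means"))
  glm_data$personal_force <- factor(glm_data$personal_force,
                                    levels = c("impersonal", "personal"))
  followups <- lapply(c(D = "grid_D", U = "grid_U"), function(resp) {
    binom <- fit_weighted_glm(glm_data, terms$between, resp,
                              weight = config$weight, family = "binomial")
    od <- overdispersion_check(binom,
                               threshold = config$overdispersion_threshold)
    quasi <- fit_weighted_glm(glm_data, terms$between, resp,
                              weight = config$weight,
                              family = "quasibinomial")
    reduced <- fit_weighted_glm(
      glm_data, .drop_term(terms$between, "instrumentality"), resp,
      weight = config$weight, family = "quasibinomial")
    list(fit = quasi, overdispersion = od,
         instrumentality_test = glm_term_test(quasi, reduced))
  })

  conv_data <- merge(conv, participants, by = "participant_id")
  conv_data$instrumentality <- factor(conv_data$instrumentality,
                                      levels = c("side_effect", "means"))
  conv_data$personal_force <- factor(conv_data$personal_force,
                                     levels = c("impersonal", "personal"))
  conv_fit <- fit_weighted_glm(conv_data, terms$between, "conventional",
                               weight = 10, family = "quasibinomial")

  ok <- !est$d_undefined
  overall <- pd_pearson(est$D[ok], est$U[ok])
  corr_cells <- data.frame(
    cell = paste(cells_tab$personal_force, cells_tab$instrumentality,
                 sep = "/"),
    r = cells_tab$r_DU, n = cells_tab$n_d_defined,
    stringsAsFactors = FALSE)
  comparisons <- if (nrow(corr_cells) >= 2) {
    pairwise_condition_comparisons(corr_cells,
                                   tail = config$correlation_tail)
  } else NULL

  power <- if (!is.null(config$power)) {
    do.call(rm_interaction_sensitivity, config$power)
  } else NULL

  bundle <- list(
    data = list(participants = participants, trials_n = nrow(trials),
                aggregates = agg, estimates = est),
    exclusions = excl$log,
    cell_summaries = cells_tab,
    congruency_contrast = contrast[c("acceptance_cong",
                                     "acceptance_cong_sd",
                                     "acceptance_incong",
                                     "acceptance_incong_sd",
                                     "odds_ratio")],
    congruency_lrt = contrast$lrt,
    mixed_logit = fit_full$coefficients,
    mixed_logit_converged = fit_full$converged,
    lrt_tests = lrts,
    sex_analysis = if (is.null(sex_analysis)) NULL else
      list(coefficients = sex_analysis$fit$coefficients,
           lrt_sex_x_parameter = sex_analysis$lrt_sex_x_parameter),
    followup_glms = lapply(followups, function(f)
      list(coefficients = f$fit$coefficients,
           dispersion = f$fit$dispersion,
           overdispersion_flag = f$overdispersion$flag,
           instrumentality_test = f$instrumentality_test)),
    conventional_analysis = list(coefficients = conv_fit$coefficients,
                                 dispersion = conv_fit$dispersion),
    correlations = list(overall = overall, cells = corr_cells,
                        comparisons = comparisons,
                        tail = config$correlation_tail),
    power = power,
    config_digest = list(seed = config$seed,
                         n_participants = nrow(participants),
                         weight = config$weight,
                         package_version =
                           as.character(utils::packageVersion("moralpd"))))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(cells_tab, file.path(output_dir, "cell_summaries.csv"),
              row.names = FALSE)
    write.csv(fit_full$coefficients,
              file.path(output_dir, "mixed_logit.csv"), row.names = FALSE)
    write.csv(excl$log, file.path(output_dir, "exclusions.csv"),
              row.names = FALSE)
    write.csv(est, file.path(output_dir, "estimates.csv"),
              row.names = FALSE)
    if (!is.null(comparisons)) {
      write.csv(comparisons,
                file.path(output_dir, "correlation_comparisons.csv"),
                row.names = FALSE)
    }
    jsonlite::write_json(bundle, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         force = TRUE)
  }
  bundle
}

#' Packaged toy datasets
#'
#' Deterministically regenerates one of the named demonstration datasets:
#' `"tiny-exp1"` (8 participants, two instrumentality conditions, personal
#' dilemmas), `"exp1"` (31 + 30 participants, instrumentality only) and
#' `"exp3"` (310 participants in four cells with 2 injected duplicate
#' submissions and 10 injected processing-time outliers, so the exclusion
#' pipeline retains 300).
#'
#' @param name fixture name.
#' @return list with `spec`, `battery`, `participants`, `trials`.
#' @export
make_fixture <- function(name = c("tiny-exp1", "exp1", "exp3")) {
  name <- match.arg(name)
  if (name == "tiny-exp1") {
    spec <- cohort_spec(cells = pd_cell_targets(1), n_per_cell = 4,
                        seed = 101L)
  } else if (name == "exp1") {
    spec <- cohort_spec(cells = pd_cell_targets(1), seed = 102L)
  } else {
    cells <- pd_cell_targets(3)
    cells$n <- c(77, 77, 78, 78)
    spec <- cohort_spec(cells = cells, n_duplicates = 2, n_outliers = 10,
                        seed = 103L)
  }
  participants <- sample_cohort(spec)
  battery <- full_battery(
    instrumentality = unique(participants$instrumentality),
    personal_force = unique(participants$personal_force))
  trials <- simulate_trials(participants, battery, seed = spec$seed + 1L)
  if (name == "exp3") {
    inj <- inject_artifacts(participants, trials, spec)
    participants <- inj$participants
    trials <- inj$trials
  }
  list(spec = spec, battery = battery, participants = participants,
       trials = trials)
}
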