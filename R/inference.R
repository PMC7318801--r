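#' Long-format data for the parameter-type analyses
#'
#' Stacks each participant's grid-rounded D and U values into one row per
#' participant x parameter type, the layout the weighted logit models
#' expect. Factors get the reference levels the result tables are written
#' against: parameter D, instrumentality side-effect, personal force
#' impersonal, sex female. Rows with undefined D are dropped (their count
#' is recorded in the `"n_dropped_d_undefined"` attribute).
#'
#' @param estimates output of [estimate_pd()].
#' @param participants participant table with the condition factors and
#'   (optionally) `sex`.
#' @return data.frame with `participant_id`, `parameter`, `value` (grid
#'   proportion), `weight`, `successes`, `failures`, condition factors.
#' @export
pd_long <- function(estimates, participants) {
  d <- merge(estimates, participants, by = "participant_id")
  mk <- function(par, val) {
    out <- data.frame(participant_id = d$participant_id,
                      parameter = par, value = val,
                      weight = d$weight,
                      stringsAsFactors = FALSE)
    out$instrumentality <- d$instrumentality
    out$personal_force <- d$personal_force
    if ("sex" %in% names(d)) out$sex <- d$sex
    out
  }
  long <- rbind(mk("D", d$grid_D), mk("U", d$grid_U))
  n_drop <- sum(is.na(long$value))
  long <- long[!is.na(long$value), , drop = FALSE]
  long$parameter <- factor(long$parameter, levels = c("D", "U"))
  long$instrumentality <- factor(long$instrumentality,
                                 levels = c("side_effect", "means"))
  long$personal_force <- factor(long$personal_force,
                                levels = c("impersonal", "personal"))
  if ("sex" %in% names(long)) {
    long$sex <- factor(long$sex, levels = c("female", "male", "other"))
    long$sex <- droplevels(long$sex)
  }
  long$participant_id <- factor(long$participant_id)
  long$successes <- as.integer(round(long$value * long$weight))
  long$failures <- long$weight - long$successes
  rownames(long) <- NULL
  attr(long, "n_dropped_d_undefined") <- n_drop
  long
}

# coefficient table with odds ratios from an estimate/SE pair
.coef_table <- function(b, se, z = b / se, p = 2 * pnorm(-abs(z))) {
  data.frame(term = names(b), b = unname(b), se = unname(se),
             z = unname(z), p = unname(p),
             or = exp(unname(b)),
             ci_lo = exp(unname(b) - 1.96 * unname(se)),
             ci_hi = exp(unname(b) + 1.96 * unname(se)),
             stringsAsFactors = FALSE)
}

#' Fit the weighted logit mixed-effects model
#'
#' Fits a binomial logit mixed model to grid proportions entered as
#' (successes, failures) pairs, with a random intercept per participant and
#' a by-participant random slope for parameter type (the only within-subject
#' factor; every participant sits in a single between-subjects condition).
#' Estimation is maximum likelihood with the Laplace approximation via
#' [lme4::glmer()]. Non-convergence and singular random-effects fits are
#' reported in the result, never silently.
#'
#' @param data long-format data from [pd_long()].
#' @param fixed one-sided formula of fixed effects, e.g.
#'   `~ parameter * instrumentality`.
#' @param random random-effects term as a string (default
#'   `"(1 + parameter | participant_id)"`; use `"(1 | participant_id)"` for
#'   intercept-only).
#' @param control optional [lme4::glmerControl()].
#' @return object of class `pd_fit`: list with `coefficients` (term, b, SE,
#'   Wald z, p, OR, 0.95 CI), `logLik`, `df`, `n_obs`, `converged`,
#'   `singular`, `family`, `dispersion` (1 for binomial), `formula`, and the
#'   underlying `model`.
#' @export
fit_mixed_logit <- function(data, fixed = ~ parameter * instrumentality,
                            random = "(1 + parameter | participant_id)",
                            control = NULL) {
  stopifnot(all(c("successes", "failures", "participant_id") %in% names(data)))
  if (min(table(data$participant_id)) < 1) stop("empty participant cells")
  rhs <- paste(paste(deparse(fixed[[2]]), collapse = " "), "+", random)
  fml <- as.formula(paste("cbind(successes, failures) ~", rhs))
  if (is.null(control)) {
    # with aggregated binomial rows (weight trials each) the usual
    # observations-vs-random-effects count check is too conservative:
    # each row carries `weight` Bernoulli trials
    control <- lme4::glmerControl(optimizer = "bobyqa",
                                  optCtrl = list(maxfun = 100000),
                                  check.nobs.vs.nRE = "ignore")
  }
  fit <- withCallingHandlers(
    lme4::glmer(fml, data = data, family = binomial(), control = control),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) {
      if (grepl("failed to converge|boundary", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  cc <- summary(fit)$coefficients
  conv <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    fit@optinfo$conv$opt == 0
  structure(list(
    coefficients = .coef_table(setNames(cc[, 1], rownames(cc)), cc[, 2]),
    logLik = as.numeric(logLik(fit)),
    df = attr(logLik(fit), "df"),
    n_obs = nrow(data),
    converged = conv,
    singular = lme4::isSingular(fit),
    family = "binomial",
    dispersion = 1,
    formula = fml,
    model = fit), class = "pd_fit")
}

#' @export
print.pd_fit <- function(x, digits = 3, ...) {
  cat("Weighted logit fit (", x$family, ")\n", sep = "")
  cat("  ", paste(deparse(x$formula), collapse = " "), "\n", sep = "")
  tab <- x$coefficients
  tab[, -1] <- lapply(tab[, -1], round, digits)
  print(tab, row.names = FALSE)
  if (!is.na(x$logLik)) cat("logLik:", round(x$logLik, 2), " df:", x$df, "\n")
  if (x$family != "binomial" || x$dispersion != 1) {
    cat("dispersion:", round(x$dispersion, 3), "\n")
  }
  if (!isTRUE(x$converged)) cat("WARNING: fit did not converge cleanly\n")
  if (isTRUE(x$singular)) cat("NOTE: singular random-effects fit\n")
  invisible(x)
}

#' Likelihood ratio test between nested fits
#'
#' `chisq = 2 * (logLik(full) - logLik(reduced))` on `df` equal to the
#' difference in parameter counts, referred to the central chi-squared
#' distribution. The reduced model must be nested in the full one (its
#' fixed-effect terms a subset, fitted to the same observations).
#'
#' @param full,reduced `pd_fit` objects from [fit_mixed_logit()].
#' @return data.frame with `chisq`, `df`, `p`, and the two formulas.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "pd_fit"), inherits(reduced, "pd_fit"))
  if (full$n_obs != reduced$n_obs) {
    stop("models were fitted to different numbers of observations")
  }
  t_full <- attr(terms(full$formula), "term.labels")
  t_red <- attr(terms(reduced$formula), "term.labels")
  if (!all(t_red %in% t_full) || full$df < reduced$df) {
    stop("reduced model is not nested in the full model")
  }
  chisq <- max(0, 2 * (full$logLik - reduced$logLik))
  df <- full$df - reduced$df
  # df = 0 only for identical specifications: no restriction to test
  p <- if (df == 0) 1 else pchisq(chisq, df, lower.tail = FALSE)
  data.frame(chisq = chisq, df = df,
             p = p,
             full = paste(deparse(full$formula), collapse = " "),
             reduced = paste(deparse(reduced$formula), collapse = " "),
             stringsAsFactors = FALSE)
}

#' Fit a weighted (quasi)binomial GLM to a single parameter
#'
#' Follow-up fixed-effects logit model for one parameter type at a time
#' (one row per participant). With `family = "quasibinomial"` the
#' dispersion is estimated as Pearson chi-squared over residual df and
#' standard errors scale by its square root — the overdispersion-robust
#' analysis used when the binomial assumption fails.
#'
#' @param data one-row-per-participant data.frame.
#' @param fixed one-sided formula of predictors, e.g.
#'   `~ instrumentality * personal_force`.
#' @param response name of the grid-proportion column (e.g. `"grid_D"`).
#' @param weight integer weight of the response grid.
#' @param family `"quasibinomial"` (default) or `"binomial"`.
#' @return a `pd_fit` object (with `dispersion` the Pearson estimate and
#'   t/z statistics in the `z` column).
#' @export
fit_weighted_glm <- function(data, fixed, response, weight = 20,
                             family = c("quasibinomial", "binomial")) {
  family <- match.arg(family)
  y <- data[[response]]
  stopifnot(!is.null(y), all(is.na(y) | (y >= 0 & y <= 1)))
  keep <- !is.na(y)
  data <- data[keep, , drop = FALSE]
  y <- y[keep]
  data$successes <- as.integer(round(y * weight))
  data$failures <- weight - data$successes
  fml <- as.formula(paste("cbind(successes, failures) ~",
                          paste(deparse(fixed[[2]]), collapse = " ")))
  fam <- if (family == "binomial") binomial() else quasibinomial()
  fit <- glm(fml, data = data, family = fam)
  if (!fit$converged) warning("GLM did not converge")
  # complete-separation symptom: huge coefficients with huge SEs
  cc <- summary(fit)$coefficients
  if (any(abs(cc[, 1]) > 15)) {
    warning("possible complete separation: extreme coefficient(s)")
  }
  disp <- sum(residuals(fit, type = "pearson")^2) / df.residual(fit)
  ll <- if (family == "binomial") as.numeric(logLik(fit)) else NA_real_
  structure(list(
    coefficients = .coef_table(setNames(cc[, 1], rownames(cc)), cc[, 2],
                               z = cc[, 3], p = cc[, 4]),
    logLik = ll,
    df = length(coef(fit)) + (family == "quasibinomial"),
    n_obs = nrow(data),
    converged = fit$converged,
    singular = FALSE,
    family = family,
    dispersion = if (family == "binomial") 1 else disp,
    pearson_dispersion = disp,
    formula = fml,
    model = fit), class = "pd_fit")
}

#' Term test for (quasi)binomial GLMs
#'
#' Compares two nested GLM fits. For the binomial family this is the
#' likelihood-ratio chi-squared test; for quasibinomial the deviance
#' difference is scaled by the estimated dispersion (a scaled chi-squared
#' test; use `test = "F"` for the F version).
#'
#' @param full,reduced `pd_fit` objects from [fit_weighted_glm()].
#' @param test `"Chisq"` (default) or `"F"`.
#' @return data.frame with the statistic, df and p-value.
#' @export
glm_term_test <- function(full, reduced, test = c("Chisq", "F")) {
  test <- match.arg(test)
  stopifnot(inherits(full$model, "glm"), inherits(reduced$model, "glm"))
  a <- anova(reduced$model, full$model, test = test)
  if (test == "Chisq") {
    dev <- a$Deviance[2]
    df <- a$Df[2]
    phi <- if (full$family == "quasibinomial") full$pearson_dispersion else 1
    stat <- dev / phi
    data.frame(chisq = stat, df = df,
               p = pchisq(stat, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(f = a$F[2], df1 = a$Df[2], df2 = df.residual(full$model),
               p = a$`Pr(>F)`[2], stringsAsFactors = FALSE)
  }
}

#' Check a binomial fit for overdispersion
#'
#' Pearson chi-squared divided by residual df; values well above 1 indicate
#' residual variance exceeding the binomial assumption, in which case the
#' quasibinomial analysis should be used.
#'
#' @param fit a `pd_fit` from [fit_weighted_glm()] (binomial family) or any
#'   fitted `glm`.
#' @param threshold dispersion above which the flag is raised (default 1.5).
#' @return list with `dispersion`, `flag`, `threshold`.
#' @export
overdispersion_check <- function(fit, threshold = 1.5) {
  model <- if (inherits(fit, "pd_fit")) fit$model else fit
  df <- df.residual(model)
  if (df <= 0) stop("no residual degrees of freedom")
  disp <- sum(residuals(model, type = "pearson")^2) / df
  list(dispersion = disp, flag = disp > threshold, threshold = threshold)
}
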