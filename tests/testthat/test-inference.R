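test_that("identical cell distributions yield near-zero fixed effects", {
  long <- fixed_effects_fixture(n_per_group = 8, b = c(0, 0, 0, 0))
  # every parameter-by-group cell sees the same balanced response pattern
  long$successes <- rep(rep(c(8L, 12L), each = 4), 4)
  long$failures <- 20L - long$successes
  fit <- fit_mixed_logit(long, fixed = ~ parameter * instrumentality)
  non_int <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  expect_true(all(abs(non_int$b) < 1e-4))
  expect_true(all(abs(non_int$z) < 0.1))
})

test_that("odds ratios and CIs are exact transforms of b and SE", {
  long <- fixed_effects_fixture()
  fit <- fit_mixed_logit(long)
  cc <- fit$coefficients
  expect_equal(cc$or, exp(cc$b), tolerance = 1e-12)
  expect_equal(cc$ci_lo, exp(cc$b - 1.96 * cc$se), tolerance = 1e-12)
  expect_equal(cc$ci_hi, exp(cc$b + 1.96 * cc$se), tolerance = 1e-12)
})

test_that("with no participant heterogeneity all routes agree", {
  # mixed logit (random effects collapse to zero), quasibinomial GLM and a
  # Newton-Raphson direct likelihood maximization on the same <= 40 rows
  long <- fixed_effects_fixture(n_per_group = 10)
  expect_lte(nrow(long), 40)

  mixed <- fit_mixed_logit(long)
  expect_true(mixed$singular)  # variance at the zero boundary

  glm_b <- fit_weighted_glm(long, ~ parameter * instrumentality, "value",
                            weight = 20, family = "binomial")
  glm_q <- fit_weighted_glm(long, ~ parameter * instrumentality, "value",
                            weight = 20, family = "quasibinomial")

  X <- stats::model.matrix(~ parameter * instrumentality, long)
  beta_oracle <- newton_logistic(X, long$successes, 20)

  expect_equal(mixed$coefficients$b, unname(beta_oracle), tolerance = 1e-6)
  expect_equal(glm_b$coefficients$b, unname(beta_oracle), tolerance = 1e-6)
  expect_equal(glm_q$coefficients$b, unname(beta_oracle), tolerance = 1e-6)
  # deterministic refit
  mixed2 <- fit_mixed_logit(long)
  expect_identical(mixed$coefficients, mixed2$coefficients)
})

test_that("a known interaction is recovered by the mixed model", {
  set.seed(314)
  b_true <- -1.2  # parameter-by-group interaction on the log-odds scale
  cover <- 0
  for (rep in 1:15) {
    n <- 40
    grp <- rep(c("side_effect", "means"), each = n / 2)
    u <- rnorm(n, 0, 0.6)
    long <- data.frame(
      participant_id = factor(rep(sprintf("s%02d", 1:n), 2)),
      parameter = factor(rep(c("D", "U"), each = n),
                         levels = c("D", "U")),
      instrumentality = factor(rep(grp, 2),
                               levels = c("side_effect", "means")))
    eta <- 0.5 + u[as.integer(long$participant_id)] -
      0.4 * (long$parameter == "U") +
      0.3 * (long$instrumentality == "means") +
      b_true * (long$parameter == "U") * (long$instrumentality == "means")
    long$successes <- rbinom(nrow(long), 20, plogis(eta))
    long$failures <- 20L - long$successes
    fit <- fit_mixed_logit(long)
    cc <- fit$coefficients
    row <- cc[cc$term == "parameterU:instrumentalitymeans", ]
    if (b_true > row$b - 1.96 * row$se && b_true < row$b + 1.96 * row$se) {
      cover <- cover + 1
    }
  }
  expect_gte(cover, 11)  # ~95% nominal coverage, generous binomial slack
})

test_that("likelihood ratio tests behave like chi-squared comparisons", {
  long <- fixed_effects_fixture(n_per_group = 10)
  full <- fit_mixed_logit(long, fixed = ~ parameter * instrumentality)
  red <- fit_mixed_logit(long, fixed = ~ parameter + instrumentality)
  out <- lrt(full, red)
  expect_equal(out$df, 1)
  expect_gte(out$chisq, 0)
  expect_equal(out$p, pchisq(out$chisq, 1, lower.tail = FALSE))

  # identical models: zero statistic, p = 1
  self <- lrt(full, full)
  expect_equal(self$chisq, 0)
  expect_equal(self$p, 1)

  # chi-squared quantile identity at the 5% point
  fake_red <- red
  fake_red$logLik <- full$logLik - 3.84 / 2
  out2 <- lrt(full, fake_red)
  expect_equal(out2$p, 0.05, tolerance = 0.002)

  expect_error(lrt(red, full), "not nested")
})

test_that("Wald z and LRT point the same way on a clear effect", {
  long <- fixed_effects_fixture(n_per_group = 10,
                                b = c(0.4, -0.8, 0.6, -1.5))
  full <- fit_mixed_logit(long)
  red <- fit_mixed_logit(long, fixed = ~ parameter + instrumentality)
  wald_p <- full$coefficients$p[
    full$coefficients$term == "parameterU:instrumentalitymeans"]
  lrt_p <- lrt(full, red)$p
  expect_true((wald_p < 0.05) == (lrt_p < 0.05))
})

test_that("overdispersed data raise the dispersion and widen SEs", {
  set.seed(88)
  n <- 60
  grp <- factor(rep(c("side_effect", "means"), each = n / 2),
                levels = c("side_effect", "means"))
  # beta-binomial style extra-binomial variation
  p <- plogis(rnorm(n, 0.3 - 0.8 * (grp == "means"), 0.9))
  d <- data.frame(instrumentality = grp,
                  value = rbinom(n, 20, p) / 20)
  q <- fit_weighted_glm(d, ~ instrumentality, "value", weight = 20,
                        family = "quasibinomial")
  b <- fit_weighted_glm(d, ~ instrumentality, "value", weight = 20,
                        family = "binomial")
  expect_gt(q$dispersion, 1.5)
  expect_true(all(q$coefficients$se > b$coefficients$se))
  expect_equal(q$coefficients$b, b$coefficients$b, tolerance = 1e-9)

  od <- overdispersion_check(b)
  expect_true(od$flag)
  # flag is monotone in the threshold
  flags <- vapply(c(1, 2, 5, 50),
                  function(th) overdispersion_check(b, th)$flag, logical(1))
  expect_true(all(diff(as.integer(flags)) <= 0))
})

test_that("model-consistent binomial data show dispersion near one", {
  set.seed(12)
  n <- 200
  grp <- factor(rep(c("a", "b"), each = n / 2))
  p <- ifelse(grp == "a", 0.6, 0.4)
  d <- data.frame(g = grp, value = rbinom(n, 20, p) / 20)
  fit <- fit_weighted_glm(d, ~ g, "value", weight = 20,
                          family = "binomial")
  od <- overdispersion_check(fit)
  expect_lt(abs(od$dispersion - 1), 0.25)
  expect_false(od$flag)
})

test_that("two-group odds ratio equals the pooled-count odds ratio", {
  d <- data.frame(g = factor(rep(c("lo", "hi"), each = 10),
                             levels = c("lo", "hi")),
                  value = rep(c(0.6, 0.8), each = 10))
  fit <- fit_weighted_glm(d, ~ g, "value", weight = 20,
                          family = "quasibinomial")
  or_hand <- (0.8 / 0.2) / (0.6 / 0.4)
  expect_equal(fit$coefficients$or[2], or_hand, tolerance = 1e-9)
})

test_that("quasibinomial term tests scale the deviance by the dispersion", {
  set.seed(77)
  n <- 80
  grp <- factor(rep(c("a", "b"), each = n / 2))
  p <- plogis(rnorm(n, 0.2 - 0.6 * (grp == "b"), 0.8))
  d <- data.frame(g = grp, value = rbinom(n, 20, p) / 20)
  full <- fit_weighted_glm(d, ~ g, "value", family = "quasibinomial")
  red <- fit_weighted_glm(d, ~ 1, "value", family = "quasibinomial")
  chi <- glm_term_test(full, red, test = "Chisq")
  f <- glm_term_test(full, red, test = "F")
  expect_equal(chi$df, 1)
  raw_dev <- red$model$deviance - full$model$deviance
  expect_equal(chi$chisq, raw_dev / full$pearson_dispersion,
               tolerance = 1e-9)
  expect_equal(f$df1, 1)
  expect_gt(f$p, 0)
})
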