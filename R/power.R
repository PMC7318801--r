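#' Power of the within-between repeated-measures ANOVA interaction
#'
#' Computes achieved power for the interaction of a g-group (between) by
#' m-measure (within) repeated-measures ANOVA from a noncentral-F
#' calculation. Under the G*Power convention for this test family the
#' noncentrality parameter is `lambda = f^2 * N * m / (1 - rho)` where
#' `rho` is the correlation among the repeated measures, with
#' `df1 = (g-1)(m-1)` and `df2 = (N-g)(m-1)`; power is the upper-tail
#' noncentral-F probability beyond the central-F critical value at `alpha`.
#' The alternative `"spss"` convention assumes the effect size already
#' absorbs the `m/(1 - rho)` factor, i.e. `lambda = f^2 * N`.
#'
#' @param partial_eta2 effect size as partial eta-squared in (0, 1)
#'   (converted internally via `f^2 = eta2 / (1 - eta2)`); give either this
#'   or `f2`.
#' @param f2 effect size as Cohen's f-squared.
#' @param n_total total sample size N.
#' @param n_groups number of between-subject groups g.
#' @param n_measures number of repeated measures m.
#' @param rho correlation among the repeated measures, in (-1, 1).
#' @param alpha significance level.
#' @param convention `"gpower"` (default) or `"spss"`.
#' @return list with `f2`, `partial_eta2`, `lambda`, `df1`, `df2`,
#'   `f_crit`, `power`.
#' @export
rm_interaction_power <- function(partial_eta2 = NULL, f2 = NULL,
                                 n_total, n_groups = 2, n_measures = 2,
                                 rho = 0, alpha = 0.05,
                                 convention = c("gpower", "spss")) {
  convention <- match.arg(convention)
  stopifnot(xor(is.null(partial_eta2), is.null(f2)),
            n_total > n_groups, n_groups >= 2, n_measures >= 2,
            rho > -1, rho < 1, alpha > 0, alpha < 1)
  if (is.null(f2)) {
    stopifnot(partial_eta2 > 0, partial_eta2 < 1)
    f2 <- partial_eta2 / (1 - partial_eta2)
  } else {
    stopifnot(f2 > 0)
    partial_eta2 <- f2 / (1 + f2)
  }
  df1 <- (n_groups - 1) * (n_measures - 1)
  df2 <- (n_total - n_groups) * (n_measures - 1)
  lambda <- if (convention == "gpower") {
    f2 * n_total * n_measures / (1 - rho)
  } else {
    f2 * n_total
  }
  f_crit <- qf(1 - alpha, df1, df2)
  power <- pf(f_crit, df1, df2, ncp = lambda, lower.tail = FALSE)
  list(f2 = f2, partial_eta2 = partial_eta2, lambda = lambda,
       df1 = df1, df2 = df2, f_crit = f_crit, power = power)
}

#' Minimum detectable effect size (sensitivity analysis)
#'
#' Solves for the smallest partial eta-squared whose achieved power (under
#' [rm_interaction_power()]) equals `target_power`, by root-finding on the
#' effect size to a power tolerance of 1e-6. Inverse-consistent with
#' [rm_interaction_power()].
#'
#' @inheritParams rm_interaction_power
#' @param target_power desired power 1 - beta, in (0, 1).
#' @return list as from [rm_interaction_power()], where `partial_eta2` is
#'   the minimum detectable effect size and `power` the achieved power at
#'   it (equal to `target_power` within 1e-6).
#' @export
#' @examples
#' s <- rm_interaction_sensitivity(n_total = 60, rho = -0.45)
#' round(s$partial_eta2, 3)
rm_interaction_sensitivity <- function(n_total, n_groups = 2,
                                       n_measures = 2, rho = 0,
                                       alpha = 0.05, target_power = 0.80,
                                       convention = c("gpower", "spss")) {
  convention <- match.arg(convention)
  stopifnot(target_power > 0, target_power < 1)
  pw <- function(f2) {
    rm_interaction_power(f2 = f2, n_total = n_total, n_groups = n_groups,
                         n_measures = n_measures, rho = rho, alpha = alpha,
                         convention = convention)$power - target_power
  }
  lo <- 1e-10; hi <- 1
  while (pw(hi) < 0 && hi < 1e6) hi <- hi * 10
  if (pw(hi) < 0) stop("target power not bracketed; check the spec")
  root <- uniroot(pw, c(lo, hi), tol = 1e-12)$root
  rm_interaction_power(f2 = root, n_total = n_total, n_groups = n_groups,
                       n_measures = n_measures, rho = rho, alpha = alpha,
                       convention = convention)
}
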