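---
title: "Process dissociation for moral dilemmas: models, decisions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process dissociation for moral dilemmas: models, decisions, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moralpd)
```

## The measurement model

Process dissociation separates two latent response tendencies by
comparing conditions in which they agree with conditions in which they
conflict. For harm-related moral dilemmas the tendencies are a
deontological inclination $D$ (reject the harmful action categorically)
and a utilitarian inclination $U$ (accept it when it maximizes overall
welfare). Each participant answers 10 *incongruent* dilemmas (acting is
harmful but maximizes benefit: the tendencies conflict) and 10
*congruent* twins (the benefit of acting is minimized: both tendencies
favor rejection).

The processing tree assumes utilitarian evaluation drives the response
with probability $U$; otherwise the response is deontological with
probability $D$. This yields

$$p(\text{unacceptable}\mid\text{congruent}) = U + (1-U)D,\qquad
  p(\text{unacceptable}\mid\text{incongruent}) = (1-U)D,$$

so both parameters are identified in closed form from the two observed
rejection proportions:

$$\hat U = \hat p_c - \hat p_i, \qquad \hat D = \hat p_i / (1 - \hat U).$$

`estimate_pd()` implements this inversion. The package deliberately does
*not* implement likelihood-based hierarchical multinomial-processing-tree
estimation: with two free parameters and two observed proportions per
participant the closed form is exact, and the downstream analyses operate
on the individual estimates.

Model assumptions worth keeping in mind: a single $(D, U)$ pair per
participant (no item heterogeneity), independence across trials, and the
specific tree ordering in which utilitarian evaluation takes precedence.
`estimate_pd()` is the exact inverse of that tree — the package's test
suite verifies the round trip at $10^{-12}$ over a dense $(D, U)$ grid —
but it cannot validate the tree itself.

## Conditioning rules for regression

Sampling error can push $\hat U$ below 0 (and, at the boundary, to 1).
Two rules condition the estimates for weighted logistic regression, in a
fixed order:

1. **Clamp.** Negative values are set to 0, the nearest meaningful value
   for a probability. The reported $D$ uses the clamped $U$ in its
   denominator (so $\hat p_c = 0.4,\ \hat p_i = 0.5$ gives $U = 0$,
   $D = 0.5$); the fully raw ratio is kept in `D_raw`.
2. **Grid rounding.** Values are rounded to the nearest multiple of
   $1/20$, so that (value × 20, (1 − value) × 20) is an integer
   (successes, failures) pair — e.g. 0.42 → 0.40 and 0.44 → 0.45. Exact
   ties round away from zero; the two conventional rounding examples do
   not constrain the tie direction, so this is a package decision,
   documented in `round_to_grid()`.

When $\hat U = 1$, $D$ is undefined; such participants are flagged and
excluded from D analyses with a logged reason, never silently zeroed.
The conventional one-dimensional measure — the proportion of
harm-accepting responses among the 10 incongruent items — uses weight 10
for the same reason.

## What the synthetic cohort emulates, and what it does not

No public trial-level dataset accompanies this design, so the generator
is a first-class, tested module rather than a test fixture. It emulates:

- **Between-participant heterogeneity** in $D$ and $U$ as independent
  logit-normal draws around condition-cell means. The population
  distribution of PD parameters is not identified by published
  summaries; the logit-normal keeps draws in $[0,1]$ with a single
  spread parameter. The default `sd_logit = 1.3` back-transforms to
  probability-scale SDs of roughly 0.2–0.3 over the plausible mean
  range, matching the magnitude of published cell SDs; any such
  calibration is approximate by construction. The cell *means* are hit
  exactly in expectation: the logit-scale location is solved numerically
  (`integrate` + `uniroot`) so the mean of the back-transformed draws
  equals the target.
- **Default cell targets** from the three study designs the package
  mirrors (`pd_cell_targets(1:3)`): a two-cell instrumentality design
  (D = 0.62/0.80, U = 0.55/0.28, n = 31/30), and two 2 × 2 designs
  crossing instrumentality with personal force (22 and 75 per cell).
  Per-condition group sizes for the first two designs are not published;
  equal splits are assumed.
- **An optional latent correlation** (`latent_cor`) between the D and U
  logits, off by default, for studying condition-dependent parameter
  correlations.
- **Total processing time** as a participant-level lognormal (default
  median 20 min, `sdlog` 0.5); the exclusion rule operates on total
  time only, so no per-trial response-time model is attempted.
- **QC artifacts**: exact-duplicate submissions and extreme total times
  (alternately a few seconds and several hours), with ground-truth
  labels for testing the exclusion rules.

Not emulated: item-level difficulty variation, sequence/habituation
effects, response biases, and any dependence of $D$ or $U$ on the
participant's sex (the sex covariate is sampled independently). Passing
tests therefore show that the *analysis machinery* is correct under the
model's own assumptions — not that real data satisfy those assumptions.

One estimator property matters when interpreting recovery checks: the
closed-form $\hat U$ is unbiased, but the clamping step shifts cell
means of the *conditioned* $U$ upward (it truncates only the left tail),
and $\hat D$ is a ratio and hence slightly biased at 10 + 10 items.
Recovery tests in this package compare cell means of the **raw**
estimates against the generator targets (±0.02 at 1,000 participants per
cell); the conditioned values are a regression-preparation step, not the
estimator.

## Presentation orders

Two constraints define a valid order of the 20 items: no more than three
consecutive items of the same congruency, and at least six other
dilemmas strictly between the two members of a pair (positional gap ≥ 7
— the literal reading of "six other dilemmas between"). The run-length
constraint is evaluated globally over the full 20-item sequence.

`generate_order()` rejection-samples uniform permutations, which makes
the accepted order exactly uniform over the valid set. The joint
constraints are rare (about 1.4 × 10⁻⁴ of uniform permutations), so the
inner loop is compiled (Rcpp) and draws from R's RNG, keeping results
reproducible from `set.seed()`. Classic designs freeze five semi-random
orders per condition; `freeze_orders()` derives any number
deterministically from one root seed, and `simulate_trials()` cycles
participants over five per condition by default.

## Exclusion rules

The pipeline order is fixed: duplicates first, then the log-time outlier
rule, then an optional minimum-time compliance rule.

- Duplicate removal keeps the first record per participant id.
- The outlier rule flags $|z| > 3$ on log total time. Natural logs are
  used; the base cancels out of the z-score. The mean and SD are
  computed **once**, on the post-duplicate-removal sample — a single
  pass, not iterative trimming. A single pass loses sensitivity when
  contamination is heavy (extremes inflate the SD estimate); at
  realistic contamination (≈3%) it identifies injected extremes exactly,
  which is what the QC acceptance test verifies.
- Designs that excluded participants for answering implausibly fast
  give no numeric threshold, so `min_total_time` exists but defaults to
  disabled.

## The weighted logit models

The per-participant grid values enter the models as (successes,
failures) integer pairs with weight 20 (10 for the conventional
measure). The primary model is a binomial logit mixed model with
parameter type (D vs. U) as the within-subject factor, the dilemma
conceptualization variables as between-subject factors, a random
intercept per participant, and a by-participant random slope for
parameter type — the only within-subject structure, since each
participant sits in one condition. Estimation is maximum likelihood with
the Laplace approximation (`lme4::glmer`, bobyqa, `maxfun` 1e5). Two
numerical notes:

- lme4's observations-versus-random-effects count check is disabled:
  with aggregated binomial rows the check (meant for Bernoulli data)
  miscounts the information per row.
- Treatment coding with reference levels D, side-effect, impersonal,
  female matches the sign conventions of the package's result tables
  ("Parameter (U)", "Instrumentality (means)", ...).

Fixed effects are evaluated both by Wald $z$ and by likelihood-ratio
tests; the test suite checks that the two agree in direction. One
structural subtlety: under R's marginality-preserving coding, removing a
two-way interaction while keeping the three-way does not reduce the
model's dimension. Each two-way interaction is therefore tested within
the model containing all two-way terms (a one-parameter restriction),
and the three-way term is tested against that model.

Follow-up per-parameter models are fixed-effects GLMs. Because
individual differences make the weight-20 counts overdispersed —
`overdispersion_check()` reports Pearson $\chi^2/\mathrm{df}$, flagged
above a configurable threshold whose default (1.5) is a package decision
— the quasibinomial family is used: SEs scale by $\sqrt{\hat\phi}$ and
term tests divide the deviance difference by $\hat\phi$ (or use the F
form).

## Correlation contrasts

Per-cell Pearson correlations between the participants' D and U values
are compared across independent cells with Fisher's r-to-z:

$$z = \frac{\operatorname{atanh}|r_1| - \operatorname{atanh}|r_2|}
{\sqrt{1/(n_1-3) + 1/(n_2-3)}}.$$

Magnitudes are compared (sign-free reporting of correlation *size*), and
in pairwise tables cells are ordered so $z \ge 0$ for the larger $|r|$.
The tail convention is explicit and configurable per call, defaulting to
two-sided, because published usage is internally mixed: some reported
$p$ values match a two-sided reading ($z = 1.19 \leftrightarrow p =
0.235$) and others a one-sided one ($z = 1.94 \leftrightarrow p =
0.026$). The report states the convention used. One published contrast
(1.45) does not recompute from the two-decimal table correlations (which
give 1.44); the unrounded correlations evidently differed. The package
documents this rather than adjusting anything.

## Power sensitivity analysis

`rm_interaction_sensitivity()` solves for the smallest partial
$\eta^2$ detectable by the within-between interaction F test of a
$g$-group × $m$-measure repeated-measures ANOVA. Under the G\*Power
convention for this family,

$$\lambda = f^2 N \frac{m}{1-\rho},\qquad
  \mathrm{df}_1 = (g-1)(m-1),\qquad \mathrm{df}_2 = (N-g)(m-1),$$

with power the upper-tail noncentral-F probability beyond the central-F
critical value. The solver brackets and root-finds on $f^2$
(`uniroot`, tolerance well below the 1e-6 power tolerance it is
documented to meet) and is inverse-consistent with
`rm_interaction_power()` by construction. At $N = 60$, $\alpha = 0.05$,
power 0.80 and $\rho = -0.45$ this gives partial $\eta^2 = 0.0893$; a
published figure of 0.088 for the same inputs corresponds to an achieved
power of 0.794 under this exact convention, i.e. the two agree to about
one unit in the third decimal but not exactly. An `"spss"` convention
switch ($\lambda = f^2 N$) is exposed because the two effect-size
conventions differ by the $m/(1-\rho)$ factor and reports rarely state
which was used. For $m = 2,\ g = 2$ the test is equivalent to a
two-sample t-test on within-person difference scores; a Monte-Carlo
check in the test suite confirms the noncentral-F power within ±0.02 at
10,000 replicates.

## Problem sizes used by the test suite

Simulation-based checks are sized to be decisive yet quick: parameter
recovery uses 1,000 participants per cell; null calibration of the
mixed-model LRT uses 200 replicates of 60 participants each (type-I
error compared against binomial 95% bounds around 0.05); the Fisher-z
null distribution uses 2,000 replicates at $n = 75$ per sample
(Kolmogorov–Smirnov against the standard normal); and order generation
is validated over 10,000 seeds against an independent brute-force
scanner.

## Known limitations

- The closed-form estimator ignores uncertainty in the per-participant
  proportions; downstream models treat grid values as data. This mirrors
  standard practice for this design but understates participant-level
  uncertainty.
- The logit-normal population model is a modelling choice, not an
  identified fact; SD calibration to published tables is approximate.
- Single-pass outlier detection is intentionally not robust to heavy
  contamination (see above).
- The pipeline's mixed models can be singular for small cells or
  near-zero random-effect variance; fits report `singular` and
  `converged` flags rather than failing, and the flags propagate to the
  JSON report.
- Group-level (pooled) PD estimation is provided for description only;
  all inferential analyses are individual-level.
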