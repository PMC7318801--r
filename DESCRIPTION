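Package: moralpd
Title: Process Dissociation Analysis of Moral Dilemma Judgments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing congruent/incongruent moral dilemma
    batteries, simulating trial-level judgment data from the
    process-dissociation processing tree, estimating per-participant
    deontological (D) and utilitarian (U) inclination parameters with the
    conditioning rules needed for weighted logistic regression, fitting
    binomial mixed-effects and quasibinomial logit models of the
    parameters, comparing D-U correlations across conditions with Fisher
    r-to-z tests, and running noncentral-F sensitivity power analyses for
    the within-between repeated-measures ANOVA interaction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
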