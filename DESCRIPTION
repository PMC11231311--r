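Package: igtrl
Title: Computational Modelling of Iowa Gambling Task Choice Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trial-level computational modelling of the Iowa
    Gambling Task (IGT): deterministic four-deck payoff schedules, the
    prospect-valence learning models with delta-rule (PVL-Delta) and
    decay-rule (PVL-DecayRI) value updating, the eight-parameter
    Value-Plus-Perseverance (VPP) model, per-subject maximum a posteriori
    and hierarchical Bayesian estimation, WAIC and PSIS-LOO model
    comparison, synthetic cohort generation with treatment effects, and
    the group-level statistics (Levene-gated t tests, paired t, mixed and
    repeated-measures ANOVA, Pearson correlation) used to contrast
    clinical groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    withr,
    car,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
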