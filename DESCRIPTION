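Package: pivotalOC
Title: Operating Characteristics of One-Trial and Two-Trial Regulatory
    Decision Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Compares regulatory decision rules for pivotal phase III drug
    trials: the classical two-trial paradigm (both trials significant at
    one-sided alpha/2), the one-trial paradigm (a single pooled analysis at
    the more stringent one-sided level (alpha/2)^2), and a random-effects
    meta-analytic rule for two trials. Provides closed-form type I error and
    power for normally distributed outcomes with known variance,
    rejection-region geometry, boundary suprema over the union and
    average-effect null hypotheses, a patient-level Monte Carlo simulator
    that validates every closed form, DerSimonian-Laird (plus ML and REML)
    between-trial heterogeneity estimation, heterogeneity simulations of the
    random-effects rule's operating characteristics, and a small command-line
    interface producing CSV/JSON grids and run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
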