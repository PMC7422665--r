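Package: gapsurv
Title: Gap-Time Analysis of Ordered Cancer-Progression Events
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated strategy for analysing ordered cancer-progression
    events (loco-regional relapse, progression, death) as dependent gap
    times in two-arm trials. Provides the gap-time decomposition of ordered
    event times, Bayesian log-normal accelerated failure time models per
    gap via conjugate Gibbs sampling, arm-stratified Bayesian regression
    linking consecutive gaps with an arm-effect-difference posterior and
    next-gap prediction, Cox proportional hazards per endpoint by maximum
    partial likelihood and random-walk Metropolis posterior sampling, a
    Kolmogorov-type supremum check of proportional hazards, Kaplan-Meier
    curves, model-comparison metrics (AIC, DIC, pD, HPD intervals), a
    synthetic two-arm trial generator, and an end-to-end report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
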