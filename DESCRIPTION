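Package: lookstack
Title: Simulation, Hierarchical Bayesian Modelling and Stacking of Looking
    Behaviour from Focal Observations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the drivers of looking (vigilance) behaviour
    recorded during 30-second focal observations of group-living animals.
    Provides a seeded synthetic-data generator for focal records, dominance
    interactions, grooming networks and gridded spatial risk layers; derived
    predictors (I&SI dominance ranks, grooming cliques, within-group social
    threats, time-since-event categories, engaged/not-engaged time budgets,
    stretched and inverted utilisation-distribution layers); a 21-model
    hypothesis set fitted with Poisson log-link (bout frequency) or
    censored, zero-truncated Gaussian (total looking duration) likelihoods
    with crossed date and individual random intercepts; and a from-scratch
    model-comparison engine: Pareto-smoothed importance-sampling
    leave-one-out cross-validation, exact leave-one-out refits, Bayesian
    stacking with two-stage re-stacking, and LOO-based Bayesian R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
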