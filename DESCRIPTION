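Package: dcemixl
Title: Discrete Choice Experiment Design and Mixed Logit Analysis of
    Community-Based Care Preferences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing discrete choice experiments
    (DCEs) in health services research: dummy-coded attribute schemes,
    D-efficient choice-set construction and evaluation, Orme sample-size
    calculation, simulation of panel choice data under a random-coefficients
    logit data-generating process, maximum simulated likelihood estimation of
    the mixed (random-parameters) logit model with Halton draws, range-method
    attribute relative importance, utility scoring and ranking of care-model
    profiles, split-sample subgroup analysis with Wald difference tests, and a
    reproducible end-to-end pipeline. Ships the choice-set design, preference
    weights and respondent marginals of a stated-preference study of
    community-based directly observed therapy for multidrug-resistant
    tuberculosis as worked fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
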