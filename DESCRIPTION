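Package: ecocredit
Title: Credit of Ecological Interactions: Rewiring Simulation and
    Monitoring-Based Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the credit of ecological interactions -- the number
    of interactions that a species reintroduction can restore in a focal
    area -- and tracks how that credit is cashed over time. Provides a
    stochastic simulator of post-release population expansion over a
    plant-occupancy arena that records cumulative interaction rewiring for
    generalist and specialist animals, and an empirical toolkit that
    estimates the credit from a flora list and a diet reference, builds
    interaction accumulation curves from monitoring logs, keeps a
    cashed/remaining credit ledger, fits asymptotic (Clench and negative
    exponential) accumulation models, estimates rewiring time, and assesses
    reintroduction success against an a priori proportion of the credit.
    A synthetic-data generator with known ground truth supports testing and
    power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
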