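Package: hhsynth
Title: Sample-Free Synthesis of Household-Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for generating household-structured synthetic populations
    directly from aggregate marginal distributions, without census microdata.
    A pluggable generator proposes batches of households, a schema and
    structural-rule validator enforces feasibility (exactly one head, no
    minors living alone, parents older than children), and discrepancies
    between target and empirical marginals are fed back to steer generation.
    Includes distributional-fit metrics (standardised root mean square error,
    Jensen-Shannon divergence, ordinal Wasserstein distance), cross-tabulation
    goodness of fit with bootstrap confidence intervals, a seeded
    deficit-proportional reference sampler, an Iterative Proportional Updating
    baseline for comparison, and a fixture generator that derives internally
    consistent (or deliberately conflicting) targets from a latent population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
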