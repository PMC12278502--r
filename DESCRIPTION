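Package: glycobo
Title: Multiobjective Bayesian Optimization for Glycosylation Reaction Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A human-in-the-loop, multiobjective Bayesian optimization toolkit
    for discovering glycosylation reaction conditions. Defines a constrained
    mixed discrete/continuous reaction-condition space (lithium salt, acid,
    solvent fractions, molecular sieves, temperature, equivalents,
    concentration, donor anomeric configuration), fits Gaussian-process
    surrogates for yield and anomeric selectivity, and proposes experiment
    batches by Pareto-front exploitation mixed with repulsive-energy
    (Steinerberger-style) exploration. Includes Pareto-front and 2-D
    hypervolume analytics, partial-dependence analysis of the fitted
    surrogates, a synthetic virtual-lab oracle for closed-loop benchmarking,
    campaign CSV input/output with a 75-experiment validation fixture, and a
    PCA-based ordinal encoding of categorical reagents from descriptor tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
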