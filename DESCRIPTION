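Package: edufert
Title: Bayesian Disaggregation of Fertility Rates by Educational Attainment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates education- and age-specific fertility rates (EAFR) and
    education-specific total fertility rates (ETFR) that are consistent with an
    authoritative age-specific fertility benchmark. A two-step pipeline first
    completes partially observed survey-derived age schedules with a
    generalized linear model, then fits a three-level hierarchical Bayesian
    model that benchmarks the weighted education-specific rates to the overall
    age-specific schedule. Includes a synthetic-data generator emulating
    survey, benchmark and education-composition inputs, holdout validation
    with credible-interval coverage reports, and a prior sensitivity suite for
    the precision hyperpriors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
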