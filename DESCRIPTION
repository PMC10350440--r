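Package: metalrisk
Title: Deterministic and Probabilistic Health Risk Assessment of Dietary Toxic Metals
Version: 0.1.0
Authors@R:
    person("metalrisk", "developers", email = "metalrisk@example.org", role = c("aut", "cre"))
Description: Tools for assessing human health risks from toxic metals in
    drinking water and food. Implements the standard US EPA oral-exposure
    chain (average daily dose, hazard quotient, hazard index, carcinogenic
    risk via a cancer slope factor), probabilistic risk characterisation by
    Monte Carlo propagation of fitted input distributions (zero-inflated
    lognormal concentrations, survey-based intake factors), goodness-of-fit
    based distribution selection (Anderson-Darling, chi-square), and
    contribution-to-variance sensitivity analysis based on rank
    correlations. Ships the published summary tables for a dietary survey
    of residents of an industrial region of northern Ningxia, China, as
    plain-text fixtures, plus a synthetic-data generator that emulates
    sample-level concentration and questionnaire data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
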