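Package: concindex
Title: Concentration Curves and Indices for Wealth-Related Health Inequity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring wealth-related inequity in health-service
    utilization from household-survey data: weighted fractional ranks,
    concentration curves with dominance classification, concentration index
    estimation by the convenient-regression, covariance and curve-area routes
    (with standard errors), covariate standardization of the index, tests for
    the change in an index between two surveys, and survey-weighted logistic
    regression with a rich-poor odds-ratio equality test. Includes a
    two-stage cluster-sampled synthetic survey generator with configurable
    wealth gradients for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
RoxygenNote: 7.3.3
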