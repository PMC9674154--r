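Package: dualvar
Title: Finite-Population Variance Estimation with Dual Auxiliary Information
Version: 0.1.0
Authors@R:
    person("dualvar", "authors", email = "dualvar@example.org", role = c("aut", "cre"))
Description: Design-based estimation of the finite-population variance of a
    study variable under simple random sampling without replacement, using a
    correlated auxiliary variable together with its population ranks ("dual"
    auxiliary information). Implements the usual, ratio, difference,
    difference-type, exponential-ratio, regression-exponential and
    dual-auxiliary regression-exponential estimators plus an improved
    ratio-in-regression exponential estimator; their first-order (Taylor)
    biases, mean squared errors and percentage relative efficiencies; exact
    minimization of the quadratic MSE surfaces in the tuning coefficients;
    pairwise efficiency conditions; and a design-based Monte-Carlo simulation
    harness with a bivariate-normal population generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
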