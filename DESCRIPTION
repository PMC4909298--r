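Package: learncurve
Title: Trial-by-Trial Estimation of Learning Curves from Binary Responses
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Moving-window estimation of learning curves from binary
    (correct/incorrect) trial responses. Implements the constant
    (binomial-proportion) model with Wald and Agresti-Coull confidence
    intervals, session-wise local logistic regression fitted by Firth's
    penalized likelihood, leave-one-out cross-validated selection of the
    window size, fixed-effects population (grand-mean) curves on the logit
    scale, local linear smoothing of continuous behavioral and
    physiological covariates, and a Monte-Carlo simulation framework for
    quantifying bias, variance, mean absolute error, and coverage of the
    estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
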