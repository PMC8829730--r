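Package: poisfl
Title: Penalized, Exact and Bayesian Poisson Regression for Sparse Count Data
Version: 0.1.0
Authors@R:
    person("poisfl", "maintainers", email = "poisfl@example.org", role = c("aut", "cre"))
Description: Poisson regression estimators that remain well defined when the
    maximum likelihood estimate does not exist (separation): Firth's
    penalized likelihood (FL), the prediction-debiased variants FLIC and
    FLAC, Bayesian estimation via Sullivan-Greenland data augmentation, and
    exact conditional inference with median-unbiased estimation. Includes a
    linear-programming separation detector with certificate direction,
    Wald and profile (penalized) likelihood confidence intervals, and a
    simulation engine for sparse-event scenario studies with events-per-
    variable design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
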