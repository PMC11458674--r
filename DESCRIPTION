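Package: medsnr
Title: Signal-to-Noise Ratios for the Indirect Effect in Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes and compares signal-to-noise ratios (SNR) of the
    indirect effect in latent-variable mediation models under structural
    equation modeling (SEM) and under path analysis with weighted composites
    (Bartlett-factor scores with population or estimated weights, and equally
    weighted composites). Provides normal-theory maximum likelihood estimation
    of the three-factor mediation model, expected-information standard errors,
    delta-method inference for the indirect effect, closed-form population
    path coefficients and asymptotic variances for composite-based path
    analysis, a delta-method correction for sampling error in estimated
    factor-score weights, and a seeded Monte Carlo engine for population and
    empirical SNR comparisons across randomly generated parameter conditions.
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
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
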