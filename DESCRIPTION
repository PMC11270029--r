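Package: parlheat
Title: Temperature and the Linguistic Complexity of Parliamentary Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how daily ambient temperature affects the
    linguistic complexity of parliamentary speeches. Implements
    readability scoring (Flesch reading ease, Flesch-Kincaid grade,
    RIX), derivation of meteorological controls (relative humidity from
    dew point via a Magnus-type saturation vapor pressure formula, wind
    speed from u/v components), temperature-bin exposure construction
    with lags and leads, multi-way fixed-effects panel regression with
    cluster-robust (CR1) inference and demographic interaction marginal
    effects, a synthetic panel generator with known injected effects for
    estimator validation, and a configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
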