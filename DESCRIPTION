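Package: wingbeatr
Title: Simulation and Evaluation of an Optical Wingbeat Sensor for
    Automated Mosquito Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying automated mosquito surveillance with an
    optical wingbeat sensor mounted on a suction trap. Simulates
    laboratory flight recordings and multi-day field capture streams of
    Aedes and Culex mosquitoes and non-target insects, extracts
    spectrogram features with automated data cleaning, trains a
    gradient-boosted genus-and-sex classifier, gates target mosquitoes
    from other insects with a multivariate Gaussian log-density
    threshold, and evaluates field performance against manual trap
    counts using count-based balanced accuracy, correlation and
    regression, and hourly-by-month activity profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
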