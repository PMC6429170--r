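Package: erpleak
Title: Information-Theoretic Evaluation of ERP Side-Channel Leakage in EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how much private information leaks from
    event-related potentials (ERPs) in electroencephalography recordings,
    in the setting of a familiarity (oddball-like) experiment where one of
    six displayed 4-digit codes is the user's real PIN. Provides a
    synthetic ERP session simulator (P300-like familiarity component,
    1/f-plus-white background noise, eye-blink artifacts, EDF/CSV export),
    a preprocessing chain (zero-phase bandpass, EOG-based artifact
    rejection, electrode selection), average/raw principal-component
    dimensionality reduction, per-class kernel or Gaussian conditional
    density models with Silverman bandwidths, and the perceived-information
    (PI) estimator with leave-one-out cross-validation and bootstrap
    confidence intervals, together with profiled, non-profiled,
    cross-user-portability and user-identification attack drivers and
    success-rate / average-rank security metrics.
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
    withr
Config/testthat/edition: 3
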