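Package: mfcoupling
Title: Maternal-Fetal RR-Interval Similarity and Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies beat-to-beat coupling between simultaneously recorded
    maternal and fetal heart rhythms. RR-interval (RRI) tachograms are screened
    for artifact-free three-minute epochs, resampled onto a common 2-s grid,
    amplitude-normalized, and scored with four similarity coefficients: the
    mean absolute (CC1) and signed (CC2) zero-lag windowed normalized
    cross-correlation, and the band-averaged Welch magnitude-squared coherence
    in the low-frequency (CLF, 0.04-0.15 Hz) and high-frequency
    (CHF, 0.15-0.25 Hz) bands. Includes normality-gated cohort statistics
    (developmental trends and group comparisons), a synthetic coupled-dyad
    generator with known coupling strength and sign for validation, and a
    small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
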