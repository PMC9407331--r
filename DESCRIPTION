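Package: citrusnmr
Title: Quantitative 1H NMR Scoring of Sweetness, Acidity and Consumer
    Acceptability in Mandarin Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the consumer acceptability of mandarin
    varieties from quantitative 1H NMR spectra of their aqueous extracts, at
    both high-field (400 MHz) and benchtop (60 MHz) spectrometer frequencies.
    Provides a synthetic spectrum generator for sucrose/glucose/fructose/citric
    acid mixtures in D2O, a reproducible processing chain (exponential
    apodization, zero filling, Fourier transformation, automated phase and
    baseline correction, chemical-shift referencing to the alpha-glucose
    anomeric proton, and derivative-based spectral alignment), fixed-window
    integration of the five marker signals anchored to the sucrose glucosyl
    anomeric proton, the sweetness-weighted sweetening-power/citric-acid ratio,
    and an ordinary least squares acceptability model with print, summary,
    predict and plot methods, plus cross-instrument equivalence comparisons and
    a declarative end-to-end pipeline with JCAMP-DX and columnar spectrum IO.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
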