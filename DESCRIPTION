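Package: diffrhythm
Title: Differential Rhythmicity Analysis by Harmonic Regression and BIC
    Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and compares diurnal rhythms in gene expression and
    metabolite time courses measured under several experimental conditions
    (e.g. genotypes or treatments). Every combination of "non-rhythmic" and
    "rhythmic with coefficients shared across conditions" is enumerated as a
    candidate harmonic-regression model, each candidate is fitted by ordinary
    least squares, and candidates are compared with the Bayesian information
    criterion and Schwarz weights. Fitted harmonics are converted to
    peak-trough amplitude, peak phase in Zeitgeber time and relative
    amplitude. A trend-augmented model family handles metabolite series with
    an overall drift, and a rescue classifier compares model assignments
    between an untreated and a treated study arm to decide whether a
    perturbed rhythm has been restored. Hypergeometric enrichment tests with
    Benjamini-Hochberg correction, a ground-truth synthetic data generator
    and a command-line interface complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
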