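Package: cchp
Title: EEG Channel Selection by Correlation of Hjorth Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies and ranks electroencephalography (EEG) channels that
    are sensitive to mental stress using the correlation coefficient of
    Hjorth parameters (CCHP). Per subject, trials labelled stress or calm
    from valence/arousal self-ratings are summarised by the three time-domain
    Hjorth parameters (activity, mobility, complexity) per channel; channels
    highly correlated with the class and weakly inter-correlated are selected
    by a correlation-based merit search, and per-subject selections are
    aggregated into an occurrence-ranked general optimal channel set. The
    package also extracts a 20-dimensional multi-domain feature vector
    (time, band power, wavelet energy, spectral entropy, fractal dimension)
    from fixed-length segments of the selected channels and evaluates them
    with SVM, k-nearest-neighbour and linear discriminant classifiers under
    subject-wise stratified 10-fold cross-validation. A synthetic EEG
    generator with planted class-sensitive channels makes the whole pipeline
    testable without access to gated datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    MASS,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
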