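Package: mwldetect
Title: EEG-Based Mental Workload Detection for Simulated Flight Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for detecting pilot mental workload (MWL)
    from few-channel wireless EEG recordings. Provides a synthetic-data
    generator for five-channel EEG with planted band-power contrasts and
    NASA-TLX workload surveys, zero-phase low-pass filtering and
    artifact-based epoch rejection, a 90-feature extractor per 2-s epoch
    (band power spectral densities, time-domain statistics, Hjorth
    parameters, sample and approximate entropy), Kruskal-Wallis and
    sequential floating forward feature selection, and cross-validated
    multi-class classification (SVM, KNN, random forest, and a
    Monte-Carlo-dropout Bayesian neural network) with macro-averaged
    metrics and region-by-band comparison harnesses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    class,
    e1071,
    randomForest,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
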