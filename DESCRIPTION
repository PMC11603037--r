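Package: periopod
Title: Intraoperative Time-Series Models for Postoperative Delirium Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end framework for predicting postoperative delirium (POD)
    from intraoperative multivariate time series. Provides long-format clinical
    event ingestion with Nu-DESC based outcome labelling, valid-range cleaning,
    availability filtering and patient-level splitting; windowed resampling to a
    regular grid with composite features, cumulative drug doses, binary
    missingness indicators, LOCF plus training-mean imputation and z-scaling;
    tabular aggregations (percentiles, Hjorth parameters, Haar wavelet
    coefficients, vectorised series); a model zoo of multilayer perceptrons,
    LSTMs, an encoder-only single-head transformer and hybrid fusion models
    trained with weighted cross-entropy or focal loss; patient-grouped nested
    cross-validation with grid and successive-halving search; bootstrap model
    comparison with a train/test-size corrected paired t-test; univariate
    Spearman screening with per-window FDR correction and mixed linear effects
    models with nested random intercepts; attention-weight interpretation and
    clinical decision-threshold scenario analysis. A synthetic perioperative
    cohort generator with controllable class signal in feature means, slopes
    and observation rates makes every stage testable without access to
    protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
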