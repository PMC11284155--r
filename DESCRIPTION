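Package: preictal
Title: Patient-Specific EEG Seizure Prediction with Firing Power Alarms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A patient-specific seizure-prediction pipeline for multichannel
    scalp or intracranial EEG: zero-phase filtering and resampling to a common
    256 Hz rate, non-overlapping 5-second windowing, extraction of 59 univariate
    linear features per channel (relative band powers, band-power ratios,
    spectral edge frequency, statistical moments, Hjorth parameters,
    decorrelation time, and db4 wavelet detail energies), SOP/SPH preictal
    labeling, class-weighted logistic classification with seizure-wise
    leave-one-out cross-validated grid search, Firing Power alarm
    regularization with a refractory period, alarm-based (sensitivity, FPR/h)
    and sample-based (SS, SP, AUC) evaluation, and surrogate-based statistical
    validation against chance. Includes a synthetic EEG generator with an
    injectable preictal band-power signature so the full pipeline is testable
    without access-restricted clinical databases, in both the continuous
    annotated-recording regime and the temporally anonymized labeled-segment
    regime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
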