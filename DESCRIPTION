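Package: fatiguecast
Title: Forecasting Driver Fatigue from Multichannel EEG and PERCLOS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end pipeline for forecasting next-time-step driver
    fatigue (PERCLOS, the fraction of time the eyelids cover the pupils)
    from multichannel EEG. Provides a seeded synthetic EEG/fatigue cohort
    generator, zero-phase bandpass filtering and polyphase resampling,
    windowed EEG feature extraction (band power, differential entropy,
    alpha/beta band-power ratio, wavelet entropy, Hurst exponent),
    sliding-window supervised dataset construction with chronological
    splits and leakage-free z-scoring, a hybrid
    CNN-Transformer-LSTM sequence-regression network with residual skips
    and ablation/baseline variants implemented in pure R with analytic
    gradients, and two evaluation paradigms: leave-one-subject-out
    cross-validation and cross-subject pretraining with within-subject
    fine-tuning.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
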