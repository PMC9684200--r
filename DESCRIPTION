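Package: semgdecode
Title: Compound Motion Decoding from Multichannel Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for decoding compound hand motions (gesture x
    wrist angle x grip-strength level, 60 classes) from eight-channel surface
    electromyography. Provides a class-conditional synthetic sEMG generator,
    the standard trial conditioning chain (linear detrend, 50 Hz IIR notch,
    20-250 Hz Butterworth bandpass), disjoint 150 ms windowing with
    chronological train/test splitting, the classic time-domain feature set
    (MAV, RMS, VAR, 4th AR coefficient, waveform length, zero crossings,
    slope sign changes), integrated 60-class decoders and triple-parallel
    classifier chains over SVM/KNN/tree/discriminant families, and the
    evaluation surfaces used in myoelectric pattern recognition (per-mode
    accuracy, confusion matrices, factor accuracies, training-proportion and
    feature-count sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    MASS,
    rpart,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
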