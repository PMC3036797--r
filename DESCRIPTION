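Package: neoseize
Title: Patient-Independent Neonatal EEG Seizure Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-channel, patient-independent seizure detection for neonatal
    EEG. Implements the full detection chain: notch filtering and anti-aliased
    downsampling to 32 Hz, segmentation into 8 s epochs with 50% overlap,
    extraction of 55 spectral, temporal and information-theoretic features per
    epoch, a Gaussian-kernel support vector machine with Platt sigmoid
    probability calibration, temporal smoothing by a central moving-average
    filter, per-channel thresholding with OR fusion across channels, and a
    collar that extends detected events in both directions. Includes
    event-based evaluation (good detection rate, false detections per hour,
    threshold sweep curves, duration-binned miss analysis), a
    leave-one-subject-out experiment driver, a synthetic multichannel
    neonatal-EEG generator with ground-truth seizure and artifact annotations,
    and EDF/CSV input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
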