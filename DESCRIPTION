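Package: mstbp
Title: Multi-Scale Multi-Task Neural Network Estimation of Continuous Blood Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cuff-less continuous blood pressure estimation from synchronized
    electrocardiogram (ECG) and photoplethysmogram (PPG) waveforms, using the
    invasive arterial blood pressure (ABP) channel only as the source of
    reference labels. Provides a physiologically shaped synthetic signal
    generator with per-beat ground truth; a preprocessing pipeline with 8-s
    segmentation, constrained ABP beat detection (amplitude limits and a 0.6-s
    peak-to-peak limit that rejects dicrotic false peaks), Daubechies-8
    discrete-wavelet denoising with soft thresholding, and [-1, 1] amplitude
    normalization; a multi-scale (kernel sizes 5/7/9) three-stream,
    multi-task one-dimensional convolutional network that regresses systolic,
    diastolic, and mean arterial pressure jointly, trained with Adam under a
    stepped learning-rate decay and L2 weight penalty; five-fold
    cross-validation; and device-validation statistics (Pearson r, ME, MAE,
    SD, AAMI verdict, BHS grading, Bland-Altman agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
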