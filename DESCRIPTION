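Package: gaitwave
Title: Smartphone IMU Gait Analysis with Wavelet Denoising and Classifier Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-sensor gait analysis for smartphone inertial recordings strapped to
    the calf. Simulates labeled accelerometer plus gyroscope walking trials with full
    ground truth, resamples heterogeneous native rates to a common 200 Hz, denoises
    signal magnitudes by symlet wavelet shrinkage with a per-level universal soft
    threshold, low-pass filters and decimates through a 4-level Mallat filter bank to
    12.5 Hz, extracts five spatio-temporal and spectral gait features (mean stride
    duration, stride regularity, cadence, and the periodogram PSD peaks of acceleration
    and angular rate), and benchmarks nine classifiers (LDA, QDA, KNN, kernel naive
    Bayes, RBF SVM, neuro-fuzzy, CART, probabilistic neural network, subtractive
    clustering Sugeno FIS) over every non-empty feature subset under repeated stratified
    cross-validation to discriminate physiological from pathological (hemiplegic) gait.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    rpart,
    stats,
    tools,
    utils,
    yaml
Suggests:
    class,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
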