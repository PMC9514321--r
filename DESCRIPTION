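Package: gazedecoder
Title: Decoding Perceptual Decisions and Confidence from Microsaccades and Pupil Size
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding trial-by-trial perceptual decisions (yes/no)
    and confidence (sure/maybe) from binocular eye-tracking recordings made
    during an adaptation-induced-blindness detection task. Implements blink
    detection and pupil preprocessing (binocular combination, linear
    interpolation, zero-phase low-pass filtering, within-session
    z-transformation), unsupervised microsaccade detection by velocity-peak
    clustering with physiological filters and main-sequence quality control,
    per-trial feature extraction over the adaptation, inter-stimulus and
    target periods, L1-regularized logistic decoders with repeated stratified
    cross-validation and grid-searched sparsity, permutation significance
    tests and JZS Bayes factors, a one-up-one-down staircase for contrast
    threshold calibration, and a synthetic-session generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
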