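Package: sdcl
Title: Shifted Delta Cepstral Features in a Reduced EMD Subspace for Lung Sound Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Feature extraction and evaluation tools for respiratory acoustics.
    Decomposes lung-sound recordings by empirical mode decomposition (EMD),
    selects the number of retained intrinsic mode functions with a wild-bootstrap
    L2 test on smoothed time-frequency surfaces, and extracts shifted delta
    cepstral coefficients in the reduced subspace (SDC-L). Includes a
    Daubechies-wavelet stationary/nonstationary denoiser, mel-frequency cepstral
    coefficients, ICBHI-style annotation handling, a seeded synthetic lung-sound
    generator (vesicular, wheeze, crackle), and a classifier-agnostic evaluation
    harness reporting accuracy, precision, recall and F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    yaml,
    jsonlite,
    e1071,
    randomForest,
    nnet,
    class,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
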