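Package: eegseizure
Title: Epileptic Seizure Detection from Single-Channel EEG with Wavelet
    Sub-Band Features and Dragonfly Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects epileptic seizure activity in single-channel EEG
    recordings. Records are band-limited, normalized, and decomposed with an
    undecimated (stationary) wavelet-packet transform into sixteen depth-4
    sub-bands; nine statistical and Hjorth descriptors per sub-band yield a
    143-element feature vector per record. A binary dragonfly algorithm
    performs wrapper feature selection against a k-nearest-neighbour
    cross-validation criterion, and a small multilayer perceptron classifies
    records as normal, interictal, or ictal. Includes a synthetic EEG
    generator emulating the three classes, readers and writers for
    Bonn-style ASCII records and feature tables, evaluation metrics
    (accuracy, sensitivity, specificity, precision, F1, Fisher score), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    class,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
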