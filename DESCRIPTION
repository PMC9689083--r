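Package: sawstream
Title: Similarity-Based Adaptive Windows for Imbalanced EEG Data Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rebalancing and online classification of heavily imbalanced
    binary data streams, motivated by chunked EEG seizure detection. The
    similarity-based adaptive window (SAW) strengthens the rare positive
    class in each arriving chunk by carrying forward recent positives that
    are close to the current chunk's positive-class centroid, subject to a
    positive-instance-age threshold, while never dropping or resampling
    negatives. Includes spectral featurization of raw EEG epochs, a
    skew-style accumulate-and-undersample baseline, incremental classifiers
    (Gaussian naive Bayes, a Hoeffding tree, an online-bagging ensemble),
    prequential (test-then-train) evaluation with per-chunk confusion
    matrices and the usual sensitivity/specificity family of metrics, and
    seeded synthetic stream and signal generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
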