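Package: slrco
Title: EEG Channel Optimization by Sparse Logistic Regression Weight Counting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects informative electroencephalogram (EEG) channels by
    training sparse Bayesian logistic classifiers with automatic relevance
    determination (ARD) on trial-wise multi-channel EEG, counting the large
    non-zero weights each channel receives within full, top-50% and top-25%
    intervals of the sorted absolute weights, and ranking channels by those
    counts, both per participant and for a pooled participant group. Rankings
    are evaluated by greedily growing a decoding queue of channels and
    tracking held-out classification accuracy, and can be compared with the
    classical correlation-coefficient channel screening baseline. A synthetic
    EEG trial generator with planted discriminative channels and spatially
    correlated noise makes the whole pipeline testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
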