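Package: crowdattn
Title: Learning Classifiers from Noisy Multi-Annotator Labels via Cross-Attention Pseudo-Labelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning-from-crowds classification: a feed-forward
    classifier trained jointly with instance-dependent annotator reliability
    scores obtained by a cross-attention mechanism, where the model's
    predicted class distribution queries the annotators' one-hot labels and
    the resulting reliability-weighted consensus serves as the training
    pseudo-label. Includes a calibrated synthetic multi-annotator benchmark,
    majority-vote and Dawid-Skene aggregation baselines, evaluation metrics
    (macro F1, reliability recovery, Friedman rank test), a cumulative
    annotator-sweep protocol, and CSV interfaces for long-format annotation
    tables.
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
    readr,
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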