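Package: cnnrules
Title: Symbolic Rule Extraction and Concept Attribution for Convolutional
    Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts compact decision-tree rule sets from convolutional
    neural network image classifiers by quantizing per-kernel activation
    norms into logical literals, assigns anatomical-region concepts to
    kernels by intersection-over-union hit rates against bounding boxes,
    supports expert intervention on the rule vocabulary, quantifies the
    relevance of kernel groups by muting and activation experiments with
    random baselines, and grounds kernel concepts in image texture features
    (gray-level co-occurrence and run-length statistics, first-order
    intensity summaries). Ships a synthetic two-class phantom generator and
    a small built-in CNN so the whole workflow runs end-to-end without
    external data or models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
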