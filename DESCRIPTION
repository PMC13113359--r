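Package: fundusformer
Title: Hierarchical Local-Global Attention Screening for Retinal Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a hierarchical transformer for automated screening of
    retinal fundus photographs. Images are standardized, masked to the retinal
    field of view and tokenized into non-overlapping patches; a stack of
    self-attention layers mixes neighborhood-restricted and global attention
    with a depth-increasing coefficient, and mean-pooled representations from
    several depths are fused into a single global descriptor driving sigmoid
    screening heads for single- and multi-disease prediction. Ships a synthetic
    fundus generator with known lesion ground truth, a seeded AdamW training
    loop with analytic gradients, and an evaluation harness covering screening
    metrics, degradation robustness, cross-domain retention and attention-map
    interpretability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
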