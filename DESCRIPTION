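Package: dualstream
Title: Dual-Stream Transformer Modelling of fMRI Time Series and Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Self-supervised dual-stream transformer framework for classifying
    subjects from region-of-interest (ROI) fMRI time series. A temporal encoder
    over the raw ROI series and a connectivity encoder over the flattened
    Pearson correlation vector are pre-trained by masked reconstruction,
    aligned in a shared embedding space with an InfoNCE contrastive objective,
    and fine-tuned through one of five fusion operators (concatenation, gating,
    cross-attention, bilinear pooling, attention pooling) with a softmax
    classifier. Includes a multi-site synthetic connectome generator with
    controlled group differences, stratified and leave-one-site-out evaluation
    protocols, multi-seed comparisons with paired t-tests, and gradient-based
    connection- and ROI-level importance scores. All neural components run on a
    self-contained reverse-mode automatic differentiation core written in base
    R and checked against finite differences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
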