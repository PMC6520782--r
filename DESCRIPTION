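Package: daesurv
Title: Denoising Autoencoder Feature Extraction and Survival Association
    for Paired Tumor Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts low-dimensional "deep features" from paired
    gene-expression and gene-level copy-number matrices with tied-weight
    denoising autoencoders (a one-input architecture per omics source and a
    two-input architecture with concatenated encodings), then carries the
    features through a clinical association and survival pipeline:
    complete-linkage hierarchical clustering of patients, Fisher/chi-square
    association tests against clinical characteristics, per-feature
    univariate Cox proportional-hazards fits, Cox-coefficient-weighted risk
    scores with quantile binarization into high/low-risk groups,
    Kaplan-Meier comparison of the groups, and trace-back of feature
    weights to ranked gene-level scores. A synthetic paired-omics generator
    with planted latent structure provides recoverable ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    survival,
    jsonlite,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
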