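Package: ecembed
Title: Hierarchy-Aware Contrastive Embeddings for Enzyme Commission Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a function-aware embedding space for enzymes so that
    nearest-neighbour label transfer places proteins with previously unseen
    four-field EC numbers into the correct EC1-EC3 functional neighbourhood.
    Provides deterministic EC annotation cleaning, EC4-grouped (unseen) and
    random (seen) train/test split construction with identity/coverage and
    evidence filters, a trainable multilayer-perceptron projection head over
    frozen protein embeddings, a hierarchical exemplar NCE objective (HiNCE)
    combining instance-level supervised contrastive loss with per-depth
    centroid classification, hard-negative mining with a periodically
    refreshed distance map, mask-augmented positive views for singleton
    classes, nearest-neighbour EC transfer, prefix-level evaluation with
    bootstrap confidence intervals, and a synthetic hierarchical fixture
    generator for fully offline end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
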