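Package: specdeduce
Title: Deductive Multimodal Transformers for Reaction Product Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a deductive super-network for identifying reaction
    products from a mixture of evidence sources. Task-specific encoder-decoder
    transformers ingest reactant/reagent structure strings and discretized
    IR, 1H-NMR, and EI-MS intensity spectra; their per-token probability
    vectors are fused by a single linear deduction layer that decodes the
    product string token-by-token. Includes dataset curation utilities
    (null-reaction augmentation, target-aware splitting, reagent-separator
    variants), teacher-forced training with a warm-up/decay schedule and
    spectral input dropping, beam-search inference, decisiveness and ablation
    probes, spectral noising, and a deterministic synthetic micro-chemistry
    so the whole pipeline is exercisable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
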