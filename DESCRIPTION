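Package: ncplaus
Title: Noun Compound Plausibility from Compositional Distributional Semantics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds window-based distributional semantic spaces from lemmatized
    corpora (positive pointwise mutual information weighting, non-negative
    matrix factorization), learns compositional representations for noun
    compounds via modifier lexical functions and full-additive models, derives
    semantic transparency measures (head and modifier proximity, constituent
    similarity, neighbourhood density, vector entropy) together with lexical
    covariates, and models human plausibility ratings with generalized
    additive models including random effects for constituents, stepwise
    selection of smooth and tensor-product terms, and post-fit model
    criticism. Ships seeded synthetic-data generators with known ground truth
    so the full pipeline can be validated end to end without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    data.table,
    methods,
    mgcv,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
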