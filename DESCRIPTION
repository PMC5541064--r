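Package: txrepo
Title: Drug Repositioning from Transcriptional Responses by Multi-Label
    Softmax Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts novel therapeutic properties of approved drugs from
    LINCS L1000-style landmark-gene perturbation profiles. Replicate
    perturbation trials are collapsed into a per-drug credible set, a
    multi-label softmax regression classifier with L2-regularised
    cross-entropy is trained by mini-batch gradient descent on first-level
    ATC labels, and the iteration-averaged probability matrix is mined for
    repositioning candidates via enrichment-ratio statistics and
    cross-network comparison against side-effect (Jaccard) and chemical
    structure (Tanimoto) similarity networks. Includes a synthetic cohort
    generator with planted latent therapeutic classes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
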