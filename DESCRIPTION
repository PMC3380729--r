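Package: pepSL
Title: Predicting Synthetic Lethal Genetic Interactions from Short Peptide
    Clusters
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts synthetic lethal genetic interactions (SLGIs) between
    proteins from amino-acid sequence alone. Proteins are decomposed into
    short overlapping peptide windows; reciprocally significant local-alignment
    matches are detected with Smith-Waterman scoring under an extreme-value
    (Karlin-Altschul) significance model fitted per window; matched peptides
    are grown into clusters by iterative profile search; and cluster-pair
    genetic-interaction probabilities are estimated by an EM algorithm under a
    noisy-OR observation model, from which protein-pair SLGI probabilities are
    predicted and evaluated by ROC analysis. Includes a synthetic proteome and
    interaction-network generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
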