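Package: tmfdti
Title: Triple Matrix Factorization for Drug-Target Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions (DTI) with a low-rank bilinear
    model A ~ F_d Theta F_t' fitted by triple matrix factorization: the
    adjacency matrix is factored as A_d A_t' while ridge regressions tie the
    latent factors to drug features (e.g. PubChem fingerprints) and target
    features (e.g. amino-acid trimer frequencies). One fitted model scores all
    four cold-start screening scenarios (pair completion, new drug, new
    target, new drug x new target) and yields interpretation matrices that
    rank the drug-feature/target-feature pairs driving interactions.
    Includes scenario-correct cross-validation (including blocked 5x5 splits
    for the double cold start), AUPR/AUC evaluation, SVD featurization of
    similarity matrices, protein k-mer featurization, and a synthetic-data
    generator with planted bilinear structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
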