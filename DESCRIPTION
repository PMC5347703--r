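Package: sipRVM
Title: Self-Interacting Protein Prediction from PSSM Bi-Gram Features
    with a Relevance Vector Machine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts self-interacting proteins (SIPs) from sequence alone.
    Protein sequences are represented by PSI-BLAST position-specific scoring
    matrices (PSSMs); each normalized PSSM is summarized by 400 bi-gram
    transition features (the adjacent-position co-occurrence mass for every
    ordered amino-acid pair), compressed by principal component analysis, and
    classified with a sparse-Bayesian relevance vector machine trained by
    evidence maximization. Includes a PSI-BLAST ASCII PSSM parser, a
    leakage-safe repeated-holdout evaluation harness with accuracy,
    sensitivity, specificity, precision, Matthews correlation and ROC/AUC,
    and synthetic generators (Dirichlet position profiles, planted bi-gram
    transition enrichment, Gaussian blobs) so the whole pipeline is testable
    without PSI-BLAST or curated interaction databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
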