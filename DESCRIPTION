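Package: gofuse
Title: Homology-Based GO-Term Prediction, Ensemble Fusion and F-max Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Protein function prediction from homology-search hit tables:
    PFP-style scoring of Gene Ontology terms from hit E-values with a
    functional-association (co-annotation) matrix and parental score
    transfer, two-level ESG scoring, the CONS weighted-consensus and FPM
    weighted frequent-pattern-mining ensemble methods, CAFA-style F-max
    precision-recall evaluation with DAG propagation and prior GO-term
    augmentation, plus deterministic synthetic fixture generators so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
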