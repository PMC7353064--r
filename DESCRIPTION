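Package: secretalk
Title: Secretome and Surfaceome Prediction and Tissue Crosstalk Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts tissue secretomes (classical signal-peptide and
    non-classical routes) and surfaceomes (transmembrane/GPI feature rules
    plus a plasma-membrane atlas compendium) from proteome gene lists and
    per-protein predictor feature tables, runs Gene Ontology
    over-representation analysis with Benjamini-Hochberg adjustment, and
    infers directed bipartite crosstalk networks linking proteins secreted
    by one tissue to cell-surface proteins of another through
    experimentally supported protein-protein interactions. Includes
    readers and writers for the standard interchange formats involved
    (proteome TSV, SignalP- and TargetP-style predictor tables, GAF 2.1,
    a minimal OBO 1.2 subset, PSI-MITAB 2.5, expression and ortholog
    tables), a deterministic synthetic-data generator with planted class
    structure, and reference fixtures for the fetal bovine adipose-muscle
    study conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
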