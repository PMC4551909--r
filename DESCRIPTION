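Package: ghis
Title: Genome-Wide Haploinsufficiency Scoring from Variation and
    Co-Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts which human genes are haploinsufficient (requiring two
    functional copies for a normal phenotype) from large-scale data sources
    that are free of study bias: a non-synonymous variation depletion score
    (NoVaDs) computed from per-gene counts of common versus rare functional
    variants in population exomes, proximity to known haploinsufficient
    genes in thresholded co-expression networks, evolutionary constraint
    (dN/dS) and the fetal-to-adult expression ratio.  The five features are
    combined by an ensemble of linear support vector machines trained on
    repeatedly sub-sampled haplosufficient gene sets, with cross-validated
    AUC filtering and genome-wide probability averaging.  Also provides a
    reference residual-variation intolerance score (RVIS), coding-sequence
    length matched null gene sets, MCC/AUC gene-set evaluation, study-bias
    diagnostics and a synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
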