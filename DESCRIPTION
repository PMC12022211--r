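Package: ribocomp
Title: Quantitative Proteomic Analysis of Ribosomal Protein Composition
    Across Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Label-free and targeted quantitative-proteomics pipeline for
    comparing the ribosomal protein (RP) composition of purified ribosomal
    fractions across tissues. Implements iBAQ protein quantification from
    specific peptides, replicate-based detection filtering, normalization to
    the total RP signal, two-class (POV/MEC) missing-value imputation on the
    log2 scale, one-way ANOVA with Benjamini-Hochberg control, empirical-Bayes
    moderated one-versus-all contrasts, and classification of RPs as stable,
    variable or tissue-specific. Companion modules provide replicate
    correlation and Ward hierarchical clustering of relative-abundance
    profiles, parallel-reaction-monitoring (PRM) isotope-dilution
    quantification with transition-level quality filters, renormalization of
    organ-level RPKM tables for protein-transcript concordance analysis, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
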