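Package: mulescan
Title: Structural Annotation and Degeneration Analysis of Transposase-Coding Mutator-Like Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects Mutator-like transposable elements (MULEs) that carry
    transposase sequence ("coding-MULEs") in genomic sequence: terminal
    inverted repeat (TIR) pairs above 75 percent identity flanked by a
    validated 8-11 bp target site duplication (TSD) with a translated
    homology hit between the TIRs. Diagnoses why elements lost coding
    capacity (nested transposable-element insertions, indels, point
    mutations), classifies transposase defects into six groups, dates
    nested LTR retroelements from LTR divergence, quantifies indel
    accumulation between best-homolog pairs (NIK/LIK and NG86 synonymous
    substitution rates), scores expression evidence from EST/flcDNA
    collections, and performs the associated contingency-table and
    two-sample comparisons. Includes a synthetic-genome generator with
    machine-readable ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
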