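Package: cusee
Title: Prediction of APOBEC3A/G C-to-U RNA Editing Sites and Downstream
    Variant Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts APOBEC3A/G-mediated C-to-U RNA editing sites in
    transcript coding sequences by combining a rules-based stem-loop
    (hairpin) scoring model with a random-forest classifier over binary
    nucleotide-window encodings, and consensus (union/intersection)
    calls. Includes an imbalanced-class benchmarking protocol (recall,
    precision, ROC/AUROC, proportional-set construction), a variant
    screen that filters ClinVar-dialect tables to exonic non-synonymous
    SNVs, resolves which SNPs correspond to C>U mRNA changes against
    coding sequences, and bins clinical significance, a MeSH-style
    hierarchy rollup for disease-heading association counts, and
    synthetic fixture generators with known ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
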