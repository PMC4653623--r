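Package: pidscreen
Title: Subtractive Pfam Screening for Plant-Interaction Determinants in
    Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics screening of protein-family (Pfam) gene
    counts between a target genome set (e.g. root nodule bacteria) and a
    negative-control genome set. Implements a subtractive quartile screen
    for over-represented families, an all-pairs Fisher's exact enrichment
    scan with Benjamini-Hochberg correction and a significance-fraction
    selection rule, evidence filters based on transcriptome induction,
    phylogenetic distribution and signal-peptide content, designation of
    candidate plant-interaction determinant (PID) families, operon-style
    co-localization detection, and a synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
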