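Package: gcicub
Title: Growth-Coupled Expression Variation and Codon Usage Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking growth-rate-dependent gene expression variation
    to codon usage bias in microbes. Computes geometric-mean codon usage bias
    scores (codon adaptation index, tRNA adaptation index) from coding
    sequences extracted out of GenBank flat files, processes condition-level
    expression compendia (filtering, replicate averaging, duplicate detection,
    absolute-abundance normalization), derives the per-gene Growth Correlation
    Index (the Pearson correlation between expression and growth rate across
    conditions) with a permutation null, fits nested linear models predicting
    codon bias from mean expression and the growth correlation index, and runs
    gene-set comparisons and over-representation analysis. Includes a
    synthetic-data generator with known ground truth so every stage can be
    validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
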