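Package: exprepro
Title: Reproducibility and Reliability Assays for Gene Expression
    Measurements
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Replicate-concordance diagnostics for gene expression matrices
    (RNA-Seq read counts, RPKM, microarray intensities) beyond the Pearson
    correlation coefficient: inter-replicate variation fractions, regression
    slopes and narrow-interval noise summaries; reproducibility coefficients
    built from ratios of the means and standard deviations of inter-treatment
    expression-ratio populations; empirical inter-replicate fold-change
    thresholds for filtering significant expression changes at a chosen
    false-positive likelihood; RPKM, library-size, reference-gene and
    quantile corrections; and ORF-length-based correction of protein
    quantities prior to protein-mRNA correlation analysis. Includes a
    seeded synthetic-data generator so every analysis is testable without
    external downloads, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
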