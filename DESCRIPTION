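Package: rateherit
Title: Evolutionary Rate Heterogeneity Between Metabolic Gene Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of evolutionary-rate heterogeneity between
    two gene classes (primary versus secondary metabolic pathway genes).
    Estimates pairwise dN, dS and dN/dS for ortholog coding-sequence pairs
    with the Nei-Gojobori (1986) counting method and Jukes-Cantor correction,
    computes per-gene architecture, GC, codon-usage (ENc), expression-level
    and tissue-specificity (tau) features from FASTA/GFF3/TSV inputs, and
    runs the class-comparison battery (Mann-Whitney U, Spearman rank
    correlation, coefficient of variation, two-proportion z, PCA with a
    loading-retention rule). A synthetic-data generator produces fully
    self-contained ortholog-pair and expression bundles with the statistical
    structure the analysis assumes, so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
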