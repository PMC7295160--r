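Package: devqtl
Title: Developmental cis-eQTL Mapping and Temporal Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how common genetic variants influence gene
    expression across brain development. Implements expression normalization
    (log2 counts per million, expressed-gene filtering, hidden-factor
    adjustment by residual principal components), finite mixtures of
    polynomial expression trajectories fitted by expectation-maximization,
    cell-type specificity scoring (tau), cis-eQTL linear-model scans on
    complete, prenatal and postnatal sample cuts with Benjamini-Hochberg
    false-discovery control, genomic-control lambda validation, a five-level
    temporal-predominance classification of eQTLs based on a Z-test contrast
    of prenatal and postnatal effect sizes, differential-variance F tests,
    and GWAS integration via minor-allele-frequency and gene-density matched
    permutation enrichment and five-hypothesis colocalization posteriors.
    Includes a synthetic-data generator with planted trajectory and eQTL
    structure so every stage can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
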