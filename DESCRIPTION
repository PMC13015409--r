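Package: tmregulome
Title: Integrative Regulatory Genomics of the Glucocorticoid Response in
    Trabecular Meshwork Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative regulatory-genomics toolkit linking histone-mark,
    ATAC and CTCF peak dynamics, enhancer chromatin-state classification,
    ROSE-style super-enhancer calling, enhancer-RNA filtering,
    promoter-capture Hi-C loop dynamics and A/B compartment shifts to GWAS
    variants, producing variant-to-gene assignments and multi-level gene-set
    intersections. Includes a fully deterministic synthetic-data generator
    that emulates the processed outputs of such a study (replicate peak sets,
    per-sample loops, compartment score tracks, count matrices, lead and
    LD-proxy variant tables, external super-enhancer and tissue-loop
    catalogs) together with a machine-readable ground-truth manifest, so
    every stage of the pipeline can be scored against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
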