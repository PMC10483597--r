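Package: lgrscan
Title: Exon-Level Germline Large Genomic Rearrangement Detection and
    Cohort Analytics for Targeted Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects germline large genomic rearrangements (LGRs; whole-exon
    deletions and duplications) from targeted-panel read depth using a
    panel-of-normals log2-ratio caller with a variance-to-previous quality
    metric and SNP zygosity integration.  Includes droplet digital PCR
    (ddPCR) Poisson copy-number estimation and exon-level concordance
    metrics with an integer confusion-matrix solver, per-sample genome
    instability metrics (tumor mutation burden, chromosomal instability,
    whole-genome duplication, microsatellite instability), rule-based
    germline variant pathogenicity classification, cohort analytics
    (patient grouping, double-hit detection, gene and pathway rate
    comparisons, co-occurrence testing, clinical tables, exon hotspot
    tallies, pathway enrichment), and a synthetic cohort generator so the
    whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
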