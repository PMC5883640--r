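Package: prophagetools
Title: Comparative Genomics of Temperate Phages and Their Quantification in
    Gut Viromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparative genomics of prophages and for their
    detection in fecal virome sequencing data. Delineates phage species and
    genera from whole-genome nucleotide identity and shared-protein content,
    detects diversity-generating retroelements (template/variable repeat
    pairs with adenine-polarized mismatches targeting the 3' end of genes),
    extracts sequence-level evidence of prophage activity (attL/attR direct
    repeats, variable packaging flanks, coverage enrichment, variable-repeat
    read hypervariability), quantifies phages in virome read sets with
    contamination-controlled presence calls, and compares phage prevalence
    and abundance between healthy and diseased cohorts with two-proportion
    z-tests and binomial mixed-effect models. A synthetic-data module
    generates genomes, cassettes, integrated hosts and cohort viromes with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    data.table,
    graphics,
    igraph,
    lme4,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
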