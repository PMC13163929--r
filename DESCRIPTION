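Package: methylmsp
Title: Tissue-Specific DNA Methylation Biomarker Discovery and
    Methylation-Specific PCR Assay Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for turning tissue-labelled DNA
    methylation microarray beta-values into hypermethylation-based PCR
    biomarker assays. Covers per-probe differential methylation with
    rank-sum tests and Benjamini-Hochberg adjustment, regional density
    filtering of CpG probes within 5 kb windows, assembly of
    differentially methylated regions, blood-background exclusion,
    in-silico bisulphite conversion with methylation-specific PCR
    primer/probe design and traffic-light scoring, assay performance
    statistics (dilution series, single-copy positivity, exact binomial
    confidence intervals, Fisher comparisons), digital PCR Poisson
    quantification, clinical group comparison, and seeded synthetic data
    generators with recorded ground truth for every input the pipeline
    consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
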