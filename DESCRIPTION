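Package: immunophen
Title: Immunofunctional Phenotyping of the Tumor Immune Microenvironment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies bulk-transcriptome tumor cohorts into three
    immunofunctional phenotypes - hot T-cell infiltrated (HTI), cold
    T-cell infiltrated (CTI), and non-inflamed (NI) - from the CD8+
    T-cell fraction and the immune cytolytic activity (CYT) score, the
    geometric mean of GZMA and PRF1 expression in transcripts per
    million. Provides percentile-threshold calibration with realized-
    fraction audits, phenotype-wise Mann-Whitney contrast panels over
    immune-cell fractions and immunomodulatory features, two-group
    differential expression with volcano categorization, pre-ranked gene
    set enrichment analysis with a permutation null and FDR q-values,
    Kaplan-Meier and log-rank survival analysis across receptor-defined
    subtypes, and a synthetic cohort generator with planted immune
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
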