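Package: mutscape
Title: Integrative Somatic Mutation Landscape Analysis for Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative analysis of somatic mutation cohorts in
    MAF format: mutation catalog construction and de-novo mutational
    signature extraction (SBS-96, DBS-78, ID-83 channels, non-negative
    matrix factorisation with cosine annotation against reference
    signatures), two tumor-mutational-burden statistics (with and without
    synonymous variants), neoantigen burden and binding-ratio scoring from
    epitope prediction tables, Kaplan-Meier and log-rank survival
    comparison with optimal dichotomisation of continuous scores by
    maximally selected rank statistics, gene-clinical association testing
    with higher/lower-mutated-gene classification for lymph-node
    metastasis, pairwise mutual-exclusivity testing, driver-gene consensus
    aggregation across external callers, and a fully parameterised
    synthetic-cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    survival,
    pracma,
    cluster,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
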