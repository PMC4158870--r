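Package: aenet
Title: Adverse Event Co-Occurrence Networks and Patient Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for adverse-event (AE) profiles extracted from
    electronic medical records. Patients are represented as tf-idf weighted AE
    vectors, stratified by cosine dissimilarity with average-linkage
    hierarchical clustering, and the resulting clusters are characterized in
    AE, drug and diagnosis space. Significantly co-occurring AE pairs are
    identified with two independent statistics: a pseudocount log2
    observed/expected co-occurrence score screened by Fisher's exact test with
    Benjamini-Hochberg false-discovery-rate control, and patient-normalized
    weighted edges filtered through the multiscale (disparity) backbone. A
    seeded synthetic cohort generator with heavy-tailed AE prevalence, planted
    patient clusters and planted correlated AE pairs supports validation
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
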