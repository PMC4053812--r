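Package: methylodyn
Title: Methylome Dynamics and 4C Interaction Analysis for Stem-Cell
    Differentiation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-CpG resolution methylomes of
    differentiating cell populations: two-state beta-binomial hidden Markov
    segmentation into hypo-methylated regions (HMRs), differentially
    methylated region (DMR) calling with CpG-count and methylation-difference
    filters, transcription-start-site and genomic-element methylation
    dynamics, differential-expression association with permutation
    enrichment tests, a multiscale 4C-seq "domainogram" interaction caller
    with quantile normalization of blind versus regular fragment ends and
    window-versus-flanks rank-sum testing, enhancer-promoter linking, and
    methylation metaprofiles around transcription-factor binding sites.
    Includes a synthetic-data generator that emits methylomes, annotations,
    expression matrices and 4C fragment tracks with planted ground truth,
    so every stage of the pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
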