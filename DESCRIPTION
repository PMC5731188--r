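Package: pedgls
Title: Pedigree-Based GLS Association Mapping, cis-eQTL Scanning and
    QTL-eQTL Colocalization
Version: 0.1.0
Authors@R: person("Dairy", "Genomics", email = "devnull@example.org",
    role = c("aut", "cre"))
Description: A generalised least-squares (GLS) single-marker association
    engine for pedigreed populations, in which the phenotypic covariance is
    partitioned into an additive genetic component (modelled by the
    pedigree-derived numerator relationship matrix) and an environmental
    component.  Includes genomic-control inflation machinery, Bonferroni and
    inflation-adjusted significance thresholds, greedy locus definition,
    cis-eQTL mapping on variance-stabilised negative-binomial read counts,
    and a chi-square-correlation colocalization procedure with
    candidate-gene triage.  Ships a gene-drop simulator of two-breed
    pedigreed dairy populations with marker LD, planted QTL and cis-eQTL
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    optparse
Config/testthat/edition: 3
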