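Package: gliomaCNS5
Title: WHO CNS5 Reclassification and Molecular Analysis of Adult Diffuse Gliomas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule engine that maps legacy (histology-only) adult diffuse
    glioma diagnoses to integrated WHO CNS5 molecular diagnoses
    (oligodendroglioma IDH-mutant 1p/19q-codeleted, astrocytoma IDH-mutant,
    glioblastoma IDH-wildtype, and the H3-altered pediatric-type exits),
    together with the downstream analyses such updates feed: hotspot mutation
    status extraction from MAF tables, pathway activation level (PAL) scoring
    with signed activator/repressor gene roles, consensus k-means and
    hierarchical clustering of expression and gene-level methylation,
    glioblastoma transcriptional subtype assignment from signature gene sets,
    Kaplan-Meier / Cox / pairwise log-rank survival comparison of diagnosis
    groups, ROC-AUC biomarker evaluation, and a synthetic TCGA-like cohort
    generator with planted ground truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
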