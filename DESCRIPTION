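Package: phasesig
Title: Cross-Species Translation of Time-Phased Fibrosis Gene Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives time-phased gene signatures from a bleomycin mouse lung
    time course, quantifies their enrichment in human idiopathic pulmonary
    fibrosis (IPF) case/control contrasts with a weighted running-sum
    enrichment score under a gene-permutation null, and characterizes the
    leading-edge genes by hypergeometric canonical-pathway enrichment. A
    synthetic-data module generates mouse time-course and human cohort studies
    with planted phased expression programs, so every stage of the workflow is
    testable against a known ground truth. Includes probe-to-gene collapse by
    maximum variance, ortholog mapping, PCA outlier screening, per-time-point
    ANOVA contrasts with Benjamini-Hochberg correction, composite
    fold-change/FDR gene ranking, phase signature construction, leading-edge
    union analysis, top-k pathway overlap, and the reverse (clinical-to-mouse)
    enrichment analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    fgsea,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pheatmap
Config/testthat/edition: 3
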