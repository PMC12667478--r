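Package: EnhancerFunnel
Title: Differential Enhancer Calling and Enhancer-Driven Oncogene
    Prioritization for Paired Tumor/Normal Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls putative enhancers from dual histone-mark
    (H3K27ac/H3K4me1) ChIP-seq peak sets with transcription start site
    exclusion and cross-sample reproducibility filtering, quantifies
    enhancer signal as RPKM, identifies cancer-gained (SOE) and
    cancer-depleted (CDE) enhancers with a paired t-test and
    Benjamini-Hochberg correction, runs saturation subsampling of the
    discovery cohort, and prioritizes enhancer-driven oncogene candidates
    through a four-stage integrative funnel (cell-type-specific
    accessibility overlap, windowed gene linking, dual differential
    expression, master transcription factor co-expression). A synthetic
    paired-cohort generator with ground-truth manifests makes the whole
    pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Epigenetics, ChIPSeq, DifferentialPeakCalling,
    GeneRegulation, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
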