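#' @import methods
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand mcols mcols<-
#' @importFrom BiocGenerics sort
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame metadata metadata<- queryHits subjectHits
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment RangedSummarizedExperiment
NULL

#' Paired tumor/normal cohort design
#'
#' Maps each patient to one tumor and one normal sample. Both sample vectors
#' are parallel to `patients`; no sample may be reused across patients.
#'
#' @slot patients character, patient identifiers (unique).
#' @slot tumor character, tumor sample ids, one per patient.
#' @slot normal character, normal sample ids, one per patient.
#'
#' @export
setClass("PairedDesign",
    representation(patients = "character",
                   tumor = "character",
                   normal = "character"))

setValidity("PairedDesign", function(object) {
    msg <- NULL
    n <- length(object@patients)
    if (length(object@tumor) != n || length(object@normal) != n)
        msg <- c(msg, "patients, tumor and normal must have equal length")
    if (anyDuplicated(object@patients))
        msg <- c(msg, "duplicated patient ids")
    all_samples <- c(object@tumor, object@normal)
    if (anyDuplicated(all_samples))
        msg <- c(msg, "a sample id is reused across pairs")
    if (is.null(msg)) TRUE else msg
})

#' Construct a PairedDesign
#'
#' @param patients character vector of patient ids.
#' @param tumor parallel character vector of tumor sample ids.
#' @param normal parallel character vector of normal sample ids.
#' @return A [PairedDesign-class] object.
#' @examples
#' PairedDesign(c("P1", "P2"), c("P1_T", "P2_T"), c("P1_N", "P2_N"))
#' @export
PairedDesign <- function(patients, tumor, normal) {
    new("PairedDesign", patients = as.character(patients),
        tumor = as.character(tumor), normal = as.character(normal))
}

#' Consensus enhancer catalog for one sample group
#'
#' Merged, disjoint enhancer regions for one group (tumor or normal), with
#' the number of contributing samples ("support") per region. Regions come
#' from merging the union of per-sample enhancer sets; regions supported by
#' fewer than `minSupport` samples have been dropped.
#'
#' @slot group character(1), "tumor" or "normal".
#' @slot regions [GenomicRanges::GRanges] with metadata columns `region_id`
#'   and `support`; disjoint and sorted.
#' @slot nSamples integer(1), cohort size the catalog was built from.
#' @slot minSupport integer(1), reproducibility threshold applied.
#'
#' @export
setClass("EnhancerCatalog",
    representation(group = "character",
                   regions = "GRanges",
                   nSamples = "integer",
                   minSupport = "integer"))

setValidity("EnhancerCatalog", function(object) {
    msg <- NULL
    gr <- object@regions
    if (!all(c("region_id", "support") %in% colnames(mcols(gr))))
        msg <- c(msg, "regions must carry region_id and support columns")
    else {
        sup <- mcols(gr)$support
        if (length(gr) && (any(sup < 1L) || any(sup > object@nSamples)))
            msg <- c(msg, "support must lie in [1, nSamples]")
        if (length(gr) && any(sup < object@minSupport))
            msg <- c(msg, "regions below minSupport must have been dropped")
    }
    if (length(gr) > 1L) {
        red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
        if (length(red) != length(gr))
            msg <- c(msg, "catalog regions must be disjoint")
    }
    if (is.null(msg)) TRUE else msg
})

#' Result of the four-stage candidate-gene funnel
#'
#' Records the surviving regions/genes at every stage of the integrative
#' prioritization funnel together with a per-gene audit table.
#'
#' Stages: 0 input SOEs; 1 SOEs overlapping cell-type-specific accessible
#' peaks; 2 protein-coding genes with a TSS within the linking window of a
#' stage-1 locus; 3 genes additionally passing both the bulk paired and the
#' cluster differential-expression filters; 4 genes additionally
#' co-expressed with all master transcription factors.
#'
#' @slot stage0SoeCount integer(1), input SOE count.
#' @slot loci [GenomicRanges::GRanges], stage-1 loci (SOE coordinates kept).
#' @slot stage2Genes,stage3Genes,stage4Genes character vectors of gene ids.
#' @slot audit data.frame, one row per stage-2 gene: filter outcomes and
#'   per-TF correlations.
#' @slot metadata list, thresholds and options the run used.
#'
#' @export
setClass("FunnelResult",
    representation(stage0SoeCount = "integer",
                   loci = "GRanges",
                   stage2Genes = "character",
                   stage3Genes = "character",
                   stage4Genes = "character",
                   audit = "data.frame",
                   metadata = "list"))

setValidity("FunnelResult", function(object) {
    msg <- NULL
    if (!all(object@stage3Genes %in% object@stage2Genes))
        msg <- c(msg, "stage3 genes must be a subset of stage2 genes")
    if (!all(object@stage4Genes %in% object@stage3Genes))
        msg <- c(msg, "stage4 genes must be a subset of stage3 genes")
    if (is.null(msg)) TRUE else msg
})

#' A simulated paired tumor/normal cohort with ground truth
#'
#' Container for everything [simulateCohort()] emits: per-sample dual-mark
#' peak sets, the region-level count experiment, the paired design, gene
#' annotation, bulk expression, cluster-specific accessible peaks, the
#' cluster single-cell matrix, and the ground-truth manifest.
#'
#' @slot samplePeaks named list; one element per sample, each a list with
#'   `k4me1` and `k27ac` GRanges plus `group` and `patient_id`.
#' @slot counts [SummarizedExperiment::SummarizedExperiment] of region
#'   counts (rowRanges = true regions, rowData `region_length`,
#'   colData `library_size`, `group`, `patient_id`).
#' @slot design [PairedDesign-class].
#' @slot genes data.frame gene annotation (gene_id, gene_name, chrom,
#'   strand, tss, biotype); `tss` is 0-based.
#' @slot expression numeric matrix, genes x bulk samples (RPKM-like).
#' @slot clusterPeaks [GenomicRanges::GRanges].
#' @slot clusterCells list with `matrix` (genes x cells) and `labels`.
#' @slot truth list, ground-truth manifest (planted ids, true log2FC,
#'   oncogene, decoys with violated-criterion labels).
#' @slot config list, the resolved [simConfig()] used.
#'
#' @export
setClass("SyntheticCohort",
    representation(samplePeaks = "list",
                   counts = "RangedSummarizedExperiment",
                   design = "PairedDesign",
                   genes = "data.frame",
                   expression = "matrix",
                   clusterPeaks = "GRanges",
                   clusterCells = "list",
                   truth = "list",
                   config = "list"))
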