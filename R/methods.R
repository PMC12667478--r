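#' @describeIn EnhancerCatalog-class the merged consensus regions (GRanges
#'   with `region_id` and `support`).
#' @export
setMethod("regions", "EnhancerCatalog", function(object) object@regions)

#' @describeIn EnhancerCatalog-class per-region sample support, named by
#'   region id.
#' @export
setMethod("support", "EnhancerCatalog", function(object) {
    stats::setNames(mcols(object@regions)$support,
                    mcols(object@regions)$region_id)
})

#' @describeIn EnhancerCatalog-class the group label ("tumor" or "normal").
#' @export
setMethod("catalogGroup", "EnhancerCatalog", function(object) object@group)

setMethod("show", "EnhancerCatalog", function(object) {
    cat("EnhancerCatalog (", object@group, ")\n", sep = "")
    cat("  regions: ", length(object@regions),
        " (min support ", object@minSupport,
        " of ", object@nSamples, " samples)\n", sep = "")
    if (length(object@regions)) {
        sup <- mcols(object@regions)$support
        cat("  support: median ", stats::median(sup),
            ", range [", min(sup), ", ", max(sup), "]\n", sep = "")
    }
    invisible(object)
})

#' @describeIn PairedDesign-class number of tumor/normal pairs.
#' @export
setMethod("nPairs", "PairedDesign", function(object) length(object@patients))

#' @describeIn PairedDesign-class patient ids.
#' @export
setMethod("patients", "PairedDesign", function(object) object@patients)

#' @describeIn PairedDesign-class tumor sample ids (patient order).
#' @export
setMethod("tumorSamples", "PairedDesign", function(object) object@tumor)

#' @describeIn PairedDesign-class normal sample ids (patient order).
#' @export
setMethod("normalSamples", "PairedDesign", function(object) object@normal)

setMethod("show", "PairedDesign", function(object) {
    cat("PairedDesign with", nPairs(object), "tumor/normal pairs\n")
    invisible(object)
})

#' @describeIn FunnelResult-class final candidate gene ids (stage 4).
#' @export
setMethod("candidates", "FunnelResult", function(object) object@stage4Genes)

#' @describeIn FunnelResult-class named integer vector of per-stage counts.
#' @export
setMethod("stageCounts", "FunnelResult", function(object) {
    c(soe = object@stage0SoeCount,
      overlap_loci = length(object@loci),
      linked_genes = length(object@stage2Genes),
      de_genes = length(object@stage3Genes),
      candidates = length(object@stage4Genes))
})

#' @describeIn FunnelResult-class per-gene audit table (one row per
#'   linked gene; filter outcomes, per-TF correlation, failing stage).
#' @export
setMethod("auditTable", "FunnelResult", function(object) object@audit)

setMethod("show", "FunnelResult", function(object) {
    sc <- stageCounts(object)
    cat("FunnelResult\n")
    cat("  SOEs in:          ", sc[["soe"]], "\n")
    cat("  overlap loci:     ", sc[["overlap_loci"]], "\n")
    cat("  linked genes:     ", sc[["linked_genes"]], "\n")
    cat("  dual-DE genes:    ", sc[["de_genes"]], "\n")
    cat("  candidates:       ", sc[["candidates"]], "\n")
    if (length(object@stage4Genes))
        cat("  ->", paste(object@stage4Genes, collapse = ", "), "\n")
    invisible(object)
})

#' @describeIn SyntheticCohort-class the ground-truth manifest list.
#' @export
setMethod("groundTruth", "SyntheticCohort", function(object) object@truth)

setMethod("show", "SyntheticCohort", function(object) {
    cat("SyntheticCohort:", nPairs(object@design), "pairs,",
        nrow(object@counts), "regions,",
        nrow(object@genes), "genes\n")
    cat("  planted SOE:", length(object@truth$planted_soe_ids),
        " CDE:", length(object@truth$planted_cde_ids), "\n")
    invisible(object)
})
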