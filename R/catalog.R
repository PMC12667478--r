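#' Call putative enhancers for one sample
#'
#' A sample's putative enhancers are its H3K27ac peaks that (i) overlap an
#' H3K4me1 peak by at least one base and (ii) lie at least
#' `tss_min_dist_bp` away from every transcription start site ("at least":
#' a peak exactly at the threshold distance is retained). By default the
#' H3K27ac peak keeps its full coordinates, since H3K27ac signal defines
#' the quantified enhancer region; `anchor = "geometric"` instead clips to
#' the geometric H3K27ac/H3K4me1 intersection.
#'
#' @param k27ac,k4me1 [GenomicRanges::GRanges] peak sets for the two marks.
#' @param tss_points data.frame with columns `chrom`, `pos` (0-based TSSs).
#' @param tss_min_dist_bp minimum TSS distance in bp (default 2500).
#' @param anchor `"k27ac"` (default) or `"geometric"`.
#' @return A [GenomicRanges::GRanges] of putative enhancers.
#' @examples
#' k27 <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(1001, 9001), c(2000, 9500)))
#' k4 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1501, 1800))
#' tss <- data.frame(chrom = "chr1", pos = 9100)
#' callSampleEnhancers(k27, k4, tss)
#' @export
callSampleEnhancers <- function(k27ac, k4me1, tss_points,
                                tss_min_dist_bp = 2500L,
                                anchor = c("k27ac", "geometric")) {
    anchor <- match.arg(anchor)
    if (tss_min_dist_bp < 0)
        stop("tss_min_dist_bp must be >= 0")
    common <- filterOverlapping(k27ac, k4me1, 1L)
    if (anchor == "geometric" && length(common)) {
        red <- mergeIntervals(k4me1)
        hits <- GenomicRanges::findOverlaps(common, red, ignore.strand = TRUE)
        clipped <- GRanges(seqnames(common)[queryHits(hits)],
            IRanges(pmax(start(common)[queryHits(hits)],
                         start(red)[subjectHits(hits)]),
                    pmin(end(common)[queryHits(hits)],
                         end(red)[subjectHits(hits)])))
        common <- mergeIntervals(clipped)
    }
    d <- distanceToPoints(common, tss_points)
    sort(common[d >= tss_min_dist_bp])
}

#' Build a consensus enhancer catalog for one group
#'
#' Merges the union of per-sample enhancer sets into disjoint regions,
#' counts for each merged region the number of samples contributing at
#' least one base of overlap (support), and drops regions supported by
#' fewer than `min_support` samples. Region ids are assigned as
#' `<group>_####` in genome order.
#'
#' @param per_sample non-empty list of [GenomicRanges::GRanges], one per
#'   sample.
#' @param group group label, `"tumor"` or `"normal"`.
#' @param min_support minimum number of supporting samples (default 2).
#' @return An [EnhancerCatalog-class].
#' @export
buildConsensus <- function(per_sample, group, min_support = 2L) {
    if (!length(per_sample))
        stop("per_sample must be a non-empty list of GRanges")
    if (min_support < 1L)
        stop("min_support must be >= 1")
    merged <- mergeIntervals(do.call(c, unname(lapply(per_sample, granges))))
    sup <- integer(length(merged))
    for (s in per_sample)
        sup <- sup + as.integer(GenomicRanges::countOverlaps(
            merged, s, ignore.strand = TRUE) > 0L)
    keep <- sup >= min_support
    merged <- merged[keep]
    mcols(merged)$region_id <- sprintf("%s_%04d", group, seq_along(merged))
    mcols(merged)$support <- sup[keep]
    new("EnhancerCatalog", group = as.character(group), regions = merged,
        nSamples = length(per_sample), minSupport = as.integer(min_support))
}

#' Read a cohort sample manifest
#'
#' @param path TSV with columns `sample_id`, `patient_id`, `group`
#'   (`tumor`/`normal`), `k4me1_path`, `k27ac_path`. Relative peak paths
#'   are resolved against the manifest's directory.
#' @return data.frame of the manifest with resolved paths.
#' @export
readSampleManifest <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    need <- c("sample_id", "patient_id", "group", "k4me1_path", "k27ac_path")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("manifest is missing columns: ", paste(miss, collapse = ", "))
    if (!all(df$group %in% c("tumor", "normal")))
        stop("manifest group must be 'tumor' or 'normal'")
    if (anyDuplicated(df$sample_id))
        stop("manifest: duplicated sample_id")
    base <- dirname(path)
    resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                  file.path(base, p))
    df$k4me1_path <- resolve(df$k4me1_path)
    df$k27ac_path <- resolve(df$k27ac_path)
    df[need]
}

#' Write an enhancer catalog as BED
#'
#' Columns: chrom, start, end, region_id, support.
#'
#' @param catalog an [EnhancerCatalog-class].
#' @param path output path.
#' @param header optional `#` header lines.
#' @return `path`, invisibly.
#' @export
writeCatalogBed <- function(catalog, path, header = NULL) {
    gr <- regions(catalog)
    mcols(gr)$name <- mcols(gr)$region_id
    mcols(gr)$score <- mcols(gr)$support
    writeBed(gr, path, header = header)
}
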