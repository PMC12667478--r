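## Genomic interval algebra. All user-facing coordinates follow the BED
## convention (0-based, half-open); internally intervals live in GRanges
## (1-based, closed), converted once at the I/O boundary. Abutting
## half-open intervals share no base and are therefore never merged
## (reduce with min.gapwidth = 0L).

#' Read a BED3+ file into a GRanges
#'
#' Reads a tab-separated BED file (0-based, half-open). `track`, `browser`
#' and `#` comment lines are skipped; columns beyond the first six are
#' ignored. Column 4, when present, is kept as metadata column `name` and
#' column 5 as `score`.
#'
#' @param path path to a BED file.
#' @return A sorted [GenomicRanges::GRanges]. Coordinates are converted to
#'   the 1-based closed convention GRanges uses; [writeBed()] converts back,
#'   so BED files round-trip bit-exactly.
#' @details Malformed records (fewer than 3 columns, non-integer
#'   coordinates, start >= end, negative start) raise an error naming the
#'   offending line number.
#' @seealso [writeBed()], [mergeIntervals()]
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("track name=demo", "chr1\t100\t200", "chr1\t150\t300"), bed)
#' readBed(bed)
#' @export
readBed <- function(path) {
    if (!file.exists(path))
        stop("BED file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines))
        return(GRanges())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("BED parse error at line ", lineno[which(nf < 3L)[1L]],
             ": fewer than 3 columns")
    chrom <- vapply(fields, `[[`, character(1), 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
    if (length(bad))
        stop("BED parse error at line ", lineno[bad[1L]],
             ": non-integer coordinates")
    bad <- which(start >= end | start < 0)
    if (length(bad))
        stop("BED parse error at line ", lineno[bad[1L]],
             ": start must satisfy 0 <= start < end")
    gr <- GRanges(chrom, IRanges(start = start + 1L, end = end))
    if (any(nf >= 4L))
        mcols(gr)$name <- ifelse(nf >= 4L,
            vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_,
                   character(1)), NA_character_)
    if (any(nf >= 5L))
        mcols(gr)$score <- suppressWarnings(as.numeric(
            vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else NA_character_,
                   character(1))))
    sort(gr)
}

#' Write a GRanges as BED
#'
#' Inverse of [readBed()]: 1-based closed GRanges coordinates are written as
#' 0-based half-open BED. A metadata column `name` (or the one named by
#' `name_col`) becomes column 4; `score` becomes column 5.
#'
#' @param gr a [GenomicRanges::GRanges].
#' @param path output path.
#' @param name_col metadata column to use as the BED name field, if present.
#' @param header optional character vector of `#`-prefixed header lines
#'   written before the records.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path, name_col = "name", header = NULL) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L,
                     end = end(gr),
                     stringsAsFactors = FALSE)
    if (name_col %in% colnames(mcols(gr))) {
        df$name <- as.character(mcols(gr)[[name_col]])
        if ("score" %in% colnames(mcols(gr)))
            df$score <- mcols(gr)$score
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (!is.null(header))
        writeLines(header, con)
    if (nrow(df))
        writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
    invisible(path)
}

#' Merge overlapping intervals
#'
#' Coalesces intervals sharing at least one base, per chromosome. Abutting
#' half-open intervals (BED `end == start` of the next) share no base and
#' are kept separate, matching bedtools semantics.
#'
#' @param gr a [GenomicRanges::GRanges].
#' @return A sorted GRanges of disjoint intervals covering the same bases.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 151), c(200, 300)))
#' mergeIntervals(gr)
#' @export
mergeIntervals <- function(gr) {
    sort(GenomicRanges::reduce(gr, min.gapwidth = 0L,
                               ignore.strand = TRUE))
}

#' Per-interval shared bases with another interval set
#'
#' For each interval of `anchor`, the number of bases also covered by the
#' union of `other`.
#'
#' @param anchor,other [GenomicRanges::GRanges] objects.
#' @return Integer vector parallel to `anchor`.
#' @export
overlapBases <- function(anchor, other) {
    red <- mergeIntervals(other)
    hits <- GenomicRanges::findOverlaps(anchor, red, ignore.strand = TRUE)
    ov <- integer(length(anchor))
    if (length(hits)) {
        w <- pmin(end(anchor)[queryHits(hits)], end(red)[subjectHits(hits)]) -
             pmax(start(anchor)[queryHits(hits)], start(red)[subjectHits(hits)]) + 1L
        agg <- tapply(w, queryHits(hits), sum)
        ov[as.integer(names(agg))] <- as.integer(agg)
    }
    ov
}

#' Keep anchor intervals overlapping another set
#'
#' Returns the subset of `anchor` intervals sharing at least
#' `min_overlap_bp` bases with the union of `other`. Anchor coordinates are
#' preserved (no clipping to the geometric intersection).
#'
#' @param anchor intervals to filter ([GenomicRanges::GRanges]).
#' @param other intervals to test against.
#' @param min_overlap_bp minimum shared bases (>= 1).
#' @return The filtered `anchor` GRanges.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 160))
#' filterOverlapping(a, b, 1)
#' @export
filterOverlapping <- function(anchor, other, min_overlap_bp = 1L) {
    if (min_overlap_bp < 1L)
        stop("min_overlap_bp must be >= 1")
    anchor[overlapBases(anchor, other) >= min_overlap_bp]
}

#' Distance from intervals to a set of genomic points
#'
#' For each interval, the minimum distance to any same-chromosome point:
#' 0 when a point lies on an occupied base of the interval, otherwise the
#' distance to the nearest occupied base (the half-open end coordinate is
#' not a base). Intervals on chromosomes with no point get `Inf`.
#'
#' @param gr a [GenomicRanges::GRanges].
#' @param points data.frame with columns `chrom` and `pos` (0-based base
#'   positions, e.g. TSSs).
#' @return Numeric vector of distances in bp, parallel to `gr`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100001, 100800))
#' distanceToPoints(gr, data.frame(chrom = "chr1", pos = 103000))
#' @export
distanceToPoints <- function(gr, points) {
    stopifnot(all(c("chrom", "pos") %in% colnames(points)))
    out <- rep(Inf, length(gr))
    if (!length(gr) || !nrow(points))
        return(out)
    s0 <- start(gr) - 1L       # first occupied base, 0-based
    e0 <- end(gr) - 1L         # last occupied base, 0-based
    chr <- as.character(seqnames(gr))
    for (cc in unique(chr)) {
        p <- sort(points$pos[points$chrom == cc])
        if (!length(p)) next
        i <- which(chr == cc)
        nearest <- function(q) {
            k <- findInterval(q, p)
            lo <- ifelse(k >= 1L, abs(q - p[pmax(k, 1L)]), Inf)
            hi <- ifelse(k < length(p), abs(p[pmin(k + 1L, length(p))] - q), Inf)
            pmin(lo, hi)
        }
        d <- pmin(nearest(s0[i]), nearest(e0[i]))
        # containment: any point on an occupied base
        k <- findInterval(s0[i] - 1L, p)    # points strictly < s0 counted
        succ <- ifelse(k < length(p), p[pmin(k + 1L, length(p))], Inf)
        d[succ <= e0[i]] <- 0
        out[i] <- d
    }
    out
}

#' Link genes to loci by a TSS window
#'
#' A gene is linked to a locus when its TSS lies within `window_bp` of the
#' locus on the same chromosome: in 0-based half-open terms the TSS must
#' fall in `[start - window_bp, end + window_bp)`, so a TSS exactly
#' `window_bp` upstream of the locus start links, while one exactly
#' `window_bp` past the end does not.
#'
#' @param loci [GenomicRanges::GRanges]; locus names are taken from a
#'   metadata column `region_id` or `name` if present, else positional ids.
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss` (0-based)
#'   and optionally `biotype`.
#' @param window_bp linking window in bp (>= 0); default 200 kb.
#' @param biotype_filter if non-`NULL`, only genes of this biotype are
#'   considered (e.g. `"protein_coding"`).
#' @return data.frame with columns `locus_id` and `gene_id`, one row per
#'   link.
#' @export
linkGenesWithin <- function(loci, genes, window_bp = 200000L,
                            biotype_filter = NULL) {
    if (window_bp < 0)
        stop("window_bp must be >= 0")
    stopifnot(all(c("gene_id", "chrom", "tss") %in% colnames(genes)))
    if (!is.null(biotype_filter)) {
        stopifnot("biotype" %in% colnames(genes))
        genes <- genes[genes$biotype == biotype_filter, , drop = FALSE]
    }
    ids <- locusIds(loci)
    if (!length(loci) || !nrow(genes))
        return(data.frame(locus_id = character(0), gene_id = character(0),
                          stringsAsFactors = FALSE))
    # TSS at 0-based p occupies 1-based base p+1; expanded locus in 1-based
    # closed coordinates is [start - window, end + window], which realizes
    # the half-open [start0 - w, end0 + w) containment rule exactly.
    pts <- GRanges(genes$chrom, IRanges(genes$tss + 1L, width = 1L))
    ext <- GRanges(seqnames(loci),
                   IRanges(pmax(1L, start(loci) - as.integer(window_bp)),
                           end(loci) + as.integer(window_bp)))
    hits <- GenomicRanges::findOverlaps(pts, ext, ignore.strand = TRUE)
    data.frame(locus_id = ids[subjectHits(hits)],
               gene_id = genes$gene_id[queryHits(hits)],
               stringsAsFactors = FALSE)
}

locusIds <- function(loci) {
    mc <- mcols(loci)
    if ("region_id" %in% colnames(mc)) as.character(mc$region_id)
    else if ("name" %in% colnames(mc)) as.character(mc$name)
    else sprintf("locus_%05d", seq_along(loci))
}
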