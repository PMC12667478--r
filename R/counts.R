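#' Assemble a region count experiment
#'
#' Packs a region x sample read-count matrix, region lengths and library
#' sizes into a [SummarizedExperiment::SummarizedExperiment] (assay
#' `"counts"`, rowData `region_length`, colData `library_size`), validating
#' the invariants the downstream tests rely on.
#'
#' @param counts integer matrix, regions x samples, with dimnames.
#' @param region_lengths bp per region (named or parallel to rows); all > 0.
#' @param library_sizes total mapped reads per sample; all > 0.
#' @param row_ranges optional [GenomicRanges::GRanges] parallel to rows.
#' @param col_data optional data.frame of extra per-sample columns
#'   (e.g. `group`, `patient_id`).
#' @return A SummarizedExperiment.
#' @export
regionCounts <- function(counts, region_lengths, library_sizes,
                         row_ranges = NULL, col_data = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must carry region ids as rownames and sample ids as colnames")
    if (any(counts < 0))
        stop("counts must be non-negative")
    if (length(region_lengths) != nrow(counts))
        stop("region_lengths must match the number of regions")
    if (length(library_sizes) != ncol(counts))
        stop("library_sizes must match the number of samples")
    if (any(region_lengths <= 0))
        stop("region_lengths must be > 0")
    if (any(library_sizes <= 0))
        stop("library_sizes must be > 0")
    cd <- S4Vectors::DataFrame(library_size = as.numeric(library_sizes),
                               row.names = colnames(counts))
    if (!is.null(col_data))
        for (nm in colnames(col_data)) cd[[nm]] <- col_data[[nm]]
    if (is.null(row_ranges)) {
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts),
            rowData = S4Vectors::DataFrame(
                region_length = as.numeric(region_lengths),
                row.names = rownames(counts)),
            colData = cd)
    } else {
        if (length(row_ranges) != nrow(counts))
            stop("row_ranges must be parallel to counts rows")
        row_ranges <- granges(row_ranges)
        names(row_ranges) <- rownames(counts)
        mcols(row_ranges)$region_length <- as.numeric(region_lengths)
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts),
            rowRanges = row_ranges, colData = cd)
    }
}

#' RPKM normalization of region counts
#'
#' `rpkm[i, j] = counts[i, j] / (length_i / 1e3 x libsize_j / 1e6)` --
#' reads per kilobase of region per million mapped reads.
#'
#' @param se a SummarizedExperiment from [regionCounts()].
#' @return Numeric matrix of the same dimensions.
#' @examples
#' se <- regionCounts(matrix(200, 1, 1, dimnames = list("r1", "s1")),
#'                    2000, 2e7)
#' rpkm(se)  # 5
#' @export
rpkm <- function(se) {
    counts <- SummarizedExperiment::assay(se, "counts")
    len <- SummarizedExperiment::rowData(se)$region_length
    lib <- SummarizedExperiment::colData(se)$library_size
    if (any(len <= 0) || any(lib <= 0))
        stop("region lengths and library sizes must be > 0")
    counts / outer(len / 1e3, lib / 1e6)
}

#' Map a count experiment onto a set of regions
#'
#' Re-keys region counts onto `universe` regions (e.g. the merged union of
#' tumor and normal catalogs): counts of all count-rows overlapping a
#' universe region by >= 1 bp are summed into it, and region lengths are
#' taken from the universe regions. Universe regions with no overlapping
#' count row raise an error listing the missing ids.
#'
#' @param se SummarizedExperiment with rowRanges (see [regionCounts()]).
#' @param universe [GenomicRanges::GRanges] with a `region_id` column.
#' @return A SummarizedExperiment keyed by universe region ids.
#' @export
mapCountsToRegions <- function(se, universe) {
    rr <- SummarizedExperiment::rowRanges(se)
    ids <- locusIds(universe)
    hits <- GenomicRanges::findOverlaps(universe, rr, ignore.strand = TRUE)
    missing <- setdiff(seq_along(universe), unique(queryHits(hits)))
    if (length(missing))
        stop("no counts overlap universe regions: ",
             paste(ids[missing], collapse = ", "))
    counts <- SummarizedExperiment::assay(se, "counts")
    agg <- rowsum(counts[subjectHits(hits), , drop = FALSE],
                  group = queryHits(hits))
    out <- matrix(0, nrow = length(universe), ncol = ncol(counts),
                  dimnames = list(ids, colnames(counts)))
    out[as.integer(rownames(agg)), ] <- agg
    regionCounts(out,
                 region_lengths = width(universe),
                 library_sizes = SummarizedExperiment::colData(se)$library_size,
                 row_ranges = granges(universe),
                 col_data = as.data.frame(
                     SummarizedExperiment::colData(se))[,
                     setdiff(colnames(SummarizedExperiment::colData(se)),
                             "library_size"), drop = FALSE])
}

#' Read a counts TSV with companion length and library-size tables
#'
#' @param counts_path TSV, first column `region_id`, remaining columns one
#'   per sample.
#' @param lengths_path TSV with columns `region_id`, `length`.
#' @param libsizes_path TSV with columns `sample_id`, `library_size`.
#' @param regions_bed optional BED of region coordinates (name = region id)
#'   used to attach rowRanges.
#' @return A SummarizedExperiment (see [regionCounts()]).
#' @export
readCounts <- function(counts_path, lengths_path, libsizes_path,
                       regions_bed = NULL) {
    cnt <- utils::read.delim(counts_path, header = TRUE, sep = "\t",
                             comment.char = "#", check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (colnames(cnt)[1L] != "region_id")
        stop("counts TSV must have 'region_id' as its first column")
    m <- as.matrix(cnt[, -1L, drop = FALSE])
    rownames(m) <- cnt$region_id
    len <- utils::read.delim(lengths_path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    lib <- utils::read.delim(libsizes_path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
    len <- stats::setNames(len$length, len$region_id)[rownames(m)]
    lib <- stats::setNames(lib$library_size, lib$sample_id)[colnames(m)]
    if (any(is.na(len)))
        stop("lengths table is missing regions present in the counts TSV")
    if (any(is.na(lib)))
        stop("library-size table is missing samples present in the counts TSV")
    rr <- NULL
    if (!is.null(regions_bed)) {
        gr <- readBed(regions_bed)
        idx <- match(rownames(m), mcols(gr)$name)
        if (any(is.na(idx)))
            stop("regions BED is missing ids present in the counts TSV")
        rr <- granges(gr[idx])
    }
    regionCounts(m, len, lib, row_ranges = rr)
}

#' Read a paired design TSV
#'
#' @param path TSV with columns `patient_id`, `tumor_sample`,
#'   `normal_sample`.
#' @return A [PairedDesign-class].
#' @export
readPairedDesign <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    need <- c("patient_id", "tumor_sample", "normal_sample")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("design is missing columns: ", paste(miss, collapse = ", "))
    PairedDesign(df$patient_id, df$tumor_sample, df$normal_sample)
}

#' Read an expression matrix TSV
#'
#' @param path TSV, first column `gene_id`, remaining columns one per
#'   sample; values are normalized expression (RPKM or equivalent).
#' @return Numeric matrix, genes x samples.
#' @export
readExpression <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (colnames(df)[1L] != "gene_id")
        stop("expression TSV must have 'gene_id' as its first column")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$gene_id
    if (any(m < 0))
        stop("expression values must be non-negative")
    m
}
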