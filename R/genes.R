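#' Read a gene annotation table
#'
#' Reads a tab-separated gene table with columns `gene_id`, `gene_name`,
#' `chrom`, `strand`, `tss`, `biotype`. `tss` is the 0-based position of
#' the transcription start site (strand-correct: on `-` genes it is the
#' annotated gene end minus one).
#'
#' @param path path to the TSV (header required; `#` lines skipped).
#' @return data.frame with those six columns.
#' @seealso [readGtfGenes()] for GTF input.
#' @export
readGeneTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    need <- c("gene_id", "gene_name", "chrom", "strand", "tss", "biotype")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("gene table is missing columns: ", paste(miss, collapse = ", "))
    if (any(df$tss < 0))
        stop("gene table: tss must be >= 0")
    if (!all(df$strand %in% c("+", "-")))
        stop("gene table: strand must be '+' or '-'")
    df[need]
}

#' Extract gene annotation from a GTF file
#'
#' Parses `gene` records from a GTF (1-based, inclusive) and converts them
#' to the package's 0-based gene table: on `+` genes the TSS is
#' `start - 1`, on `-` genes it is `end - 1`.
#'
#' @param path path to a GTF file.
#' @return data.frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `strand`, `tss`, `biotype`.
#' @export
readGtfGenes <- function(path) {
    gtf <- rtracklayer::import(path, format = "gtf")
    gtf <- gtf[gtf$type == "gene"]
    if (!length(gtf))
        stop("no 'gene' records found in ", path)
    strand <- as.character(strand(gtf))
    if (any(!strand %in% c("+", "-")))
        stop("GTF gene records must be stranded")
    mc <- mcols(gtf)
    getAttr <- function(col, fallback) {
        if (col %in% colnames(mc)) as.character(mc[[col]]) else fallback
    }
    gene_id <- getAttr("gene_id", sprintf("gene_%05d", seq_along(gtf)))
    data.frame(gene_id = gene_id,
               gene_name = getAttr("gene_name", gene_id),
               chrom = as.character(seqnames(gtf)),
               strand = strand,
               tss = ifelse(strand == "+", start(gtf) - 1L, end(gtf) - 1L),
               biotype = getAttr("gene_biotype", "protein_coding"),
               stringsAsFactors = FALSE)
}

#' TSS point set of a gene table
#'
#' @param genes data.frame as returned by [readGeneTable()].
#' @return data.frame with columns `chrom`, `pos` (0-based), suitable for
#'   [distanceToPoints()].
#' @export
geneTssPoints <- function(genes) {
    data.frame(chrom = genes$chrom, pos = genes$tss,
               stringsAsFactors = FALSE)
}
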