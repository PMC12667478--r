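#' Stage 1: SOEs overlapping cell-type-specific accessible peaks
#'
#' Keeps SOE intervals sharing at least one base with any cluster-specific
#' peak; SOE coordinates are preserved.
#'
#' @param soes [GenomicRanges::GRanges] of called SOEs.
#' @param cluster_peaks [GenomicRanges::GRanges] of cluster-specific
#'   accessible peaks.
#' @return The overlapping subset of `soes`.
#' @export
celltypeOverlapStage <- function(soes, cluster_peaks) {
    if (!length(soes)) return(soes)
    filterOverlapping(soes, cluster_peaks, 1L)
}

#' Stage 3a: bulk paired differential-expression filter
#'
#' Per gene, a Wilcoxon signed-rank test across patient pairs, BH
#' adjustment over all genes, and a group-mean log2 fold change (with the
#' RPKM pseudocount). Genes with `log2fc > deg_log2fc` and
#' `padj < deg_padj` (strict) pass.
#'
#' @param expr genes x samples expression matrix (normalized, >= 0).
#' @param design a [PairedDesign-class] (>= 2 pairs).
#' @param cfg a [thresholdConfig()].
#' @return data.frame per gene: `gene_id`, `log2fc`, `stat`, `p`, `padj`,
#'   `pass`.
#' @export
bulkDeFilter <- function(expr, design, cfg = thresholdConfig()) {
    if (nPairs(design) < 2L)
        stop("at least 2 pairs are required")
    miss <- setdiff(c(tumorSamples(design), normalSamples(design)),
                    colnames(expr))
    if (length(miss))
        stop("design references samples absent from expression: ",
             paste(miss, collapse = ", "))
    tum <- expr[, tumorSamples(design), drop = FALSE]
    nor <- expr[, normalSamples(design), drop = FALSE]
    wt <- lapply(seq_len(nrow(expr)), function(i)
        wilcoxonSignedRank(tum[i, ], nor[i, ]))
    p <- vapply(wt, `[[`, numeric(1), "p.value")
    W <- vapply(wt, `[[`, numeric(1), "statistic")
    padj <- bhAdjust(p)
    pc <- cfg$pseudocount
    log2fc <- log2((rowMeans(tum) + pc) / (rowMeans(nor) + pc))
    data.frame(gene_id = rownames(expr),
               log2fc = unname(log2fc),
               stat = W, p = p, padj = padj,
               pass = unname(log2fc) > cfg$deg_log2fc & padj < cfg$deg_padj,
               stringsAsFactors = FALSE)
}

#' Stage 3b: cluster differential-expression filter
#'
#' Either consumes a precomputed per-gene cluster DE table (columns
#' `gene_id`, `log2fc`, `p_adjusted`) or computes one from a genes x cells
#' matrix with cluster labels: per gene, a Wilcoxon rank-sum test of the
#' target cluster's cells against all others, adjustment per
#' `cfg$cluster_adjust` (Bonferroni by default for this stage), and
#' `log2fc = log2((mean_in + pc) / (mean_out + pc))`. Genes with
#' `log2fc > cluster_log2fc` and `p_adjusted < deg_padj` pass.
#'
#' @param cluster_de precomputed table, or `NULL` to compute from a matrix.
#' @param cells genes x cells matrix (required when `cluster_de` is NULL).
#' @param labels per-cell cluster labels, parallel to `ncol(cells)`.
#' @param target target cluster label (must exist in `labels`).
#' @param cfg a [thresholdConfig()].
#' @return data.frame per gene: `gene_id`, `log2fc`, `p`, `p_adjusted`,
#'   `pass` (plus `adjust_method`).
#' @export
clusterDeFilter <- function(cluster_de = NULL, cells = NULL, labels = NULL,
                            target = NULL, cfg = thresholdConfig()) {
    if (is.null(cluster_de)) {
        stopifnot(!is.null(cells), !is.null(labels), !is.null(target))
        if (length(labels) != ncol(cells))
            stop("labels must be parallel to the cell columns")
        if (!target %in% labels)
            stop("unknown cluster label: ", target)
        inside <- labels == target
        wt <- lapply(seq_len(nrow(cells)), function(i)
            wilcoxonRankSum(cells[i, inside], cells[i, !inside]))
        p <- vapply(wt, `[[`, numeric(1), "p.value")
        padj <- if (identical(cfg$cluster_adjust, "BH")) bhAdjust(p)
                else stats::p.adjust(p, method = "bonferroni")
        pc <- cfg$pseudocount
        log2fc <- log2((rowMeans(cells[, inside, drop = FALSE]) + pc) /
                       (rowMeans(cells[, !inside, drop = FALSE]) + pc))
        cluster_de <- data.frame(gene_id = rownames(cells),
                                 log2fc = unname(log2fc),
                                 p = p, p_adjusted = padj,
                                 adjust_method = if (identical(cfg$cluster_adjust, "BH"))
                                     "BH" else "bonferroni",
                                 stringsAsFactors = FALSE)
    } else {
        need <- c("gene_id", "log2fc", "p_adjusted")
        miss <- setdiff(need, colnames(cluster_de))
        if (length(miss))
            stop("cluster DE table is missing columns: ",
                 paste(miss, collapse = ", "))
    }
    cluster_de$pass <- cluster_de$log2fc > cfg$cluster_log2fc &
        cluster_de$p_adjusted < cfg$deg_padj
    cluster_de
}

#' Stage 4: master-TF co-expression filter
#'
#' For every candidate x TF pair, a correlation (Pearson by default)
#' across tumor samples with its two-sided p (t transform, df = n - 2),
#' BH-adjusted within each TF's candidate list. A candidate is kept iff
#' for ALL TFs `r > coexpr_r` and `padj < coexpr_padj` (the intersection
#' of the per-TF sets). Zero-variance candidates get `r = NA` and fail
#' with a flag rather than erroring.
#'
#' @param expr genes x samples expression matrix; columns restricted to
#'   tumor samples by the caller.
#' @param tf_ids gene ids of the master TFs (all must be rows of `expr`).
#' @param candidates candidate gene ids (rows of `expr`).
#' @param cfg a [thresholdConfig()].
#' @return list with `kept` (character vector) and `table` (long
#'   data.frame: `gene_id`, `tf`, `r`, `p`, `padj`, `pass`).
#' @export
coexpressionFilter <- function(expr, tf_ids, candidates,
                               cfg = thresholdConfig()) {
    miss <- setdiff(tf_ids, rownames(expr))
    if (length(miss))
        stop("TF ids absent from expression: ", paste(miss, collapse = ", "))
    if (ncol(expr) < 3L)
        stop("co-expression requires >= 3 samples")
    candidates <- intersect(candidates, rownames(expr))
    if (!length(candidates))
        return(list(kept = character(0),
                    table = data.frame(gene_id = character(0),
                                       tf = character(0), r = numeric(0),
                                       p = numeric(0), padj = numeric(0),
                                       pass = logical(0))))
    tabs <- lapply(tf_ids, function(tf) {
        v <- expr[tf, ]
        ct <- lapply(candidates, function(g)
            correlationTest(expr[g, ], v, method = cfg$coexpr_method))
        r <- vapply(ct, `[[`, numeric(1), "r")
        p <- vapply(ct, `[[`, numeric(1), "p.value")
        ok <- !is.na(p)
        padj <- rep(NA_real_, length(p))
        if (any(ok)) padj[ok] <- bhAdjust(p[ok])
        data.frame(gene_id = candidates, tf = tf, r = r, p = p, padj = padj,
                   pass = !is.na(r) & r > cfg$coexpr_r &
                          !is.na(padj) & padj < cfg$coexpr_padj,
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, tabs)
    pass_all <- tapply(tab$pass, tab$gene_id, all)
    kept <- candidates[candidates %in% names(pass_all)[pass_all]]
    list(kept = kept, table = tab)
}

#' Run the four-stage candidate-gene funnel
#'
#' Composes the prioritization stages: (1) SOEs overlapping
#' cluster-specific accessible peaks; (2) protein-coding genes whose TSS
#' lies within `link_window_bp` of a stage-1 locus; (3) genes passing both
#' the bulk paired DE filter and the cluster DE filter ("specific
#' upregulation", logical AND); (4) genes co-expressed with all master
#' TFs across tumor samples. Deterministic given its inputs.
#'
#' @param soes [GenomicRanges::GRanges] of called SOEs (ids in `region_id`
#'   or `name`).
#' @param cluster_peaks [GenomicRanges::GRanges].
#' @param genes gene annotation data.frame (see [readGeneTable()]).
#' @param expr genes x samples bulk expression matrix.
#' @param design a [PairedDesign-class]; co-expression uses its tumor
#'   samples only.
#' @param tf_ids master TF gene ids.
#' @param cluster_de,cells,labels,target cluster DE inputs, passed to
#'   [clusterDeFilter()].
#' @param cfg a [thresholdConfig()].
#' @param biotype biotype retained at the linking stage.
#' @return A [FunnelResult-class].
#' @export
runFunnel <- function(soes, cluster_peaks, genes, expr, design, tf_ids,
                      cluster_de = NULL, cells = NULL, labels = NULL,
                      target = NULL, cfg = thresholdConfig(),
                      biotype = "protein_coding") {
    loci <- tryCatch(celltypeOverlapStage(soes, cluster_peaks),
                     error = function(e) stop("funnel stage overlap: ",
                                              conditionMessage(e)))
    links <- tryCatch(
        linkGenesWithin(loci, genes, cfg$link_window_bp, biotype),
        error = function(e) stop("funnel stage linking: ",
                                 conditionMessage(e)))
    stage2 <- sort(unique(links$gene_id))
    bulk <- tryCatch(bulkDeFilter(expr, design, cfg),
                     error = function(e) stop("funnel stage bulk DE: ",
                                              conditionMessage(e)))
    clus <- tryCatch(
        clusterDeFilter(cluster_de, cells, labels, target, cfg),
        error = function(e) stop("funnel stage cluster DE: ",
                                 conditionMessage(e)))
    bulk_pass <- bulk$gene_id[bulk$pass]
    clus_pass <- clus$gene_id[clus$pass]
    stage3 <- stage2[stage2 %in% bulk_pass & stage2 %in% clus_pass]
    tumor_expr <- expr[, tumorSamples(design), drop = FALSE]
    coex <- tryCatch(coexpressionFilter(tumor_expr, tf_ids, stage3, cfg),
                     error = function(e) stop("funnel stage co-expression: ",
                                              conditionMessage(e)))
    stage4 <- sort(coex$kept)

    audit <- data.frame(gene_id = stage2,
                        linked = TRUE,
                        bulk_de = stage2 %in% bulk_pass,
                        cluster_de = stage2 %in% clus_pass,
                        stringsAsFactors = FALSE)
    audit$coexpressed <- audit$gene_id %in% stage4
    for (tf in tf_ids) {
        sub <- coex$table[coex$table$tf == tf, ]
        audit[[paste0("r_", tf)]] <- sub$r[match(audit$gene_id, sub$gene_id)]
    }
    audit$failed_stage <- ifelse(!audit$bulk_de, "bulk_de",
                          ifelse(!audit$cluster_de, "cluster_de",
                          ifelse(!audit$coexpressed, "coexpression",
                                 "pass")))
    new("FunnelResult",
        stage0SoeCount = length(soes),
        loci = loci,
        stage2Genes = stage2,
        stage3Genes = sort(stage3),
        stage4Genes = stage4,
        audit = audit,
        metadata = list(link_window_bp = cfg$link_window_bp,
                        link_to = cfg$link_to,
                        biotype = biotype,
                        deg_log2fc = cfg$deg_log2fc,
                        deg_padj = cfg$deg_padj,
                        cluster_log2fc = cfg$cluster_log2fc,
                        cluster_adjust = cfg$cluster_adjust,
                        coexpr_r = cfg$coexpr_r,
                        coexpr_padj = cfg$coexpr_padj,
                        coexpr_method = cfg$coexpr_method,
                        coexpr_samples = "tumor",
                        tf_ids = tf_ids))
}
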