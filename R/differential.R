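#' Analysis thresholds
#'
#' Bundles every tunable cutoff of the pipeline with its default:
#' \describe{
#'   \item{tss_min_dist_bp}{2500 — minimum enhancer-to-TSS distance (bp).}
#'   \item{min_support}{2 — samples an enhancer must be reproducible in.}
#'   \item{enh_log2fc}{0.75 — |log2(Tumor/Normal)| beyond which an
#'     enhancer is SOE/CDE (strict inequality).}
#'   \item{enh_padj}{0.05 — BH-adjusted p cutoff for enhancers.}
#'   \item{deg_log2fc, deg_padj}{1.0 / 0.05 — bulk differential expression.}
#'   \item{cluster_log2fc}{1.0 — cluster-vs-rest expression fold change
#'     (0.25 is the conventional single-cell alternative).}
#'   \item{cluster_adjust}{"bonferroni" — adjustment for the cluster DE
#'     stage ("BH" optional).}
#'   \item{link_window_bp}{200000 — gene-linking window.}
#'   \item{coexpr_r, coexpr_padj}{0.5 / 0.05 — master-TF co-expression.}
#'   \item{pseudocount}{0.01 — RPKM pseudocount used inside log2.}
#'   \item{anchor}{"k27ac" — common-peak anchoring (see
#'     [callSampleEnhancers()]).}
#'   \item{log2fc_mode}{"group_mean" — log2FC as the ratio of group mean
#'     RPKMs (+pseudocount); "paired_mean" averages per-pair log ratios.}
#'   \item{link_to}{"tss" — gene linking by TSS; "gene_body" is exposed
#'     for audit but TSS is the default.}
#'   \item{coexpr_method}{"pearson" ("spearman" optional).}
#' }
#'
#' @param ... named overrides of the defaults above.
#' @return A named list of thresholds (class `"thresholdConfig"`).
#' @export
thresholdConfig <- function(...) {
    cfg <- list(tss_min_dist_bp = 2500L,
                min_support = 2L,
                enh_log2fc = 0.75,
                enh_padj = 0.05,
                deg_log2fc = 1.0,
                deg_padj = 0.05,
                cluster_log2fc = 1.0,
                cluster_adjust = "bonferroni",
                link_window_bp = 200000L,
                coexpr_r = 0.5,
                coexpr_padj = 0.05,
                pseudocount = 0.01,
                anchor = "k27ac",
                log2fc_mode = "group_mean",
                link_to = "tss",
                coexpr_method = "pearson")
    dots <- list(...)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
        stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
    num <- c("tss_min_dist_bp", "min_support", "enh_log2fc", "enh_padj",
             "deg_log2fc", "deg_padj", "cluster_log2fc", "link_window_bp",
             "coexpr_r", "coexpr_padj", "pseudocount")
    if (any(unlist(cfg[num]) < 0))
        stop("thresholds must be >= 0")
    for (pp in c("enh_padj", "deg_padj", "coexpr_padj"))
        if (cfg[[pp]] <= 0 || cfg[[pp]] >= 1)
            stop(pp, " must lie in (0, 1)")
    class(cfg) <- "thresholdConfig"
    cfg
}

designMatrices <- function(se, design) {
    samp <- colnames(se)
    miss <- setdiff(c(tumorSamples(design), normalSamples(design)), samp)
    if (length(miss))
        stop("design references samples absent from the counts: ",
             paste(miss, collapse = ", "))
    list(tumor = match(tumorSamples(design), samp),
         normal = match(normalSamples(design), samp))
}

#' Call differential enhancers (SOE/CDE)
#'
#' Per region: RPKM, paired t-test on `log2(RPKM + pseudocount)` across
#' patient pairs, BH adjustment over the tested universe, and log2 fold
#' change as `log2((mean tumor RPKM + pc) / (mean normal RPKM + pc))`.
#' Classes use strict inequalities: `log2fc > enh_log2fc` and
#' `padj < enh_padj` is `SOE` (cancer-gained); `log2fc < -enh_log2fc` and
#' `padj < enh_padj` is `CDE` (cancer-depleted); all else `NS`.
#'
#' @param se region count SummarizedExperiment (see [regionCounts()]).
#' @param design a [PairedDesign-class] (>= 2 pairs).
#' @param universe region ids to test; defaults to all rows of `se`. Ids
#'   absent from `se` raise an error listing them.
#' @param cfg a [thresholdConfig()].
#' @return A [S4Vectors::DataFrame] with one row per universe region:
#'   `region_id`, `mean_rpkm_tumor`, `mean_rpkm_normal`, `log2fc`, `stat`,
#'   `p`, `padj`, `klass`; thresholds recorded in `metadata()`.
#' @export
callDifferentialEnhancers <- function(se, design, universe = rownames(se),
                                      cfg = thresholdConfig()) {
    if (nPairs(design) < 2L)
        stop("at least 2 pairs are required")
    missing <- setdiff(universe, rownames(se))
    if (length(missing))
        stop("universe regions absent from counts: ",
             paste(missing, collapse = ", "))
    se <- se[universe, ]
    idx <- designMatrices(se, design)
    rk <- rpkm(se)
    pc <- cfg$pseudocount
    lg <- log2(rk + pc)
    d <- lg[, idx$tumor, drop = FALSE] - lg[, idx$normal, drop = FALSE]
    tt <- rowPairedT(d)
    padj <- bhAdjust(tt$p)
    mt <- rowMeans(rk[, idx$tumor, drop = FALSE])
    mn <- rowMeans(rk[, idx$normal, drop = FALSE])
    log2fc <- if (identical(cfg$log2fc_mode, "paired_mean"))
        rowMeans(d)
    else
        log2((mt + pc) / (mn + pc))
    klass <- rep("NS", length(universe))
    klass[log2fc > cfg$enh_log2fc & padj < cfg$enh_padj] <- "SOE"
    klass[log2fc < -cfg$enh_log2fc & padj < cfg$enh_padj] <- "CDE"
    out <- S4Vectors::DataFrame(region_id = universe,
                                mean_rpkm_tumor = unname(mt),
                                mean_rpkm_normal = unname(mn),
                                log2fc = unname(log2fc),
                                stat = unname(tt$t),
                                p = unname(tt$p),
                                padj = unname(padj),
                                klass = klass,
                                row.names = universe)
    metadata(out) <- list(test = "paired_t_on_log2_rpkm",
                          pseudocount = pc,
                          log2fc_mode = cfg$log2fc_mode,
                          enh_log2fc = cfg$enh_log2fc,
                          enh_padj = cfg$enh_padj,
                          adjust = "BH",
                          n_pairs = nPairs(design))
    out
}

#' Region ids of a given differential class
#'
#' @param diff result of [callDifferentialEnhancers()].
#' @param klass `"SOE"` or `"CDE"`.
#' @return Character vector of region ids.
#' @export
differentialRegions <- function(diff, klass = c("SOE", "CDE")) {
    klass <- match.arg(klass)
    diff$region_id[diff$klass == klass]
}

## replicate seed scheme: documented, stable across platforms, < 2^31
saturationSeed <- function(seed, k, rep) {
    (as.integer(seed) %% 1000003L) * 2048L + as.integer(k) * 64L +
        as.integer(rep)
}

#' Saturation analysis of SOE discovery
#'
#' The SOE set called on the full cohort is the reference. For each
#' subsample size `k`, `n_replicates` subsets of `k` patient pairs are
#' drawn without replacement (replicate seeds derived from `seed` as
#' `(seed mod 1000003) * 2048 + k * 64 + replicate`), the differential
#' caller is rerun on each subset, and recovery is the fraction of
#' reference SOEs re-identified. An empty reference yields recovery 1 for
#' every replicate, with a warning flag in the result.
#'
#' @param se,design,universe,cfg as in [callDifferentialEnhancers()].
#' @param k_values subsample sizes, each in `[2, nPairs(design)]`.
#' @param n_replicates replicates per k (>= 1).
#' @param seed master seed; identical seeds give identical results.
#' @return data.frame with one row per (k, replicate): `k`, `replicate`,
#'   `recovery`, plus attributes `summary` (per-k mean/sd) and
#'   `empty_reference` flag.
#' @export
saturationAnalysis <- function(se, design, universe = rownames(se),
                               cfg = thresholdConfig(),
                               k_values = seq(2L, nPairs(design), by = 2L),
                               n_replicates = 25L, seed = 1L) {
    n <- nPairs(design)
    if (any(k_values < 2L | k_values > n))
        stop("k_values must lie in [2, nPairs]")
    if (n_replicates < 1L)
        stop("n_replicates must be >= 1")
    ref <- differentialRegions(
        callDifferentialEnhancers(se, design, universe, cfg), "SOE")
    empty_ref <- length(ref) == 0L
    if (empty_ref)
        warning("reference SOE set is empty; recovery reported as 1")
    rows <- list()
    for (k in k_values) {
        for (r in seq_len(n_replicates)) {
            if (k == n) {
                pick <- seq_len(n)
            } else {
                rng_state <- .Random.seed_save()
                set.seed(saturationSeed(seed, k, r))
                pick <- sort(sample.int(n, k))
                .Random.seed_restore(rng_state)
            }
            sub <- PairedDesign(patients(design)[pick],
                                tumorSamples(design)[pick],
                                normalSamples(design)[pick])
            soe <- differentialRegions(
                callDifferentialEnhancers(se, sub, universe, cfg), "SOE")
            rec <- if (empty_ref) 1 else
                length(intersect(soe, ref)) / length(ref)
            rows[[length(rows) + 1L]] <-
                data.frame(k = k, replicate = r, recovery = rec)
        }
    }
    out <- do.call(rbind, rows)
    summ <- do.call(rbind, lapply(split(out, out$k), function(g) {
        data.frame(k = g$k[1L], mean = mean(g$recovery),
                   sd = if (nrow(g) > 1L) stats::sd(g$recovery) else 0,
                   n_replicates = nrow(g))
    }))
    rownames(summ) <- NULL
    attr(out, "summary") <- summ
    attr(out, "empty_reference") <- empty_ref
    attr(out, "seed") <- seed
    out
}

.Random.seed_save <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.Random.seed_restore <- function(state) {
    if (!is.null(state))
        assign(".Random.seed", state, envir = globalenv())
    invisible(NULL)
}
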