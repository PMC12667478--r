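## Independent brute-force oracles and small fixture builders shared by
## the unit and acceptance tests. The oracles deliberately avoid the code
## paths they check: per-base boolean arrays instead of interval algebra,
## full enumeration instead of distribution functions.

library(GenomicRanges)

## GRanges from 0-based half-open (chrom, start, end) triples
gr0 <- function(chrom, start0, end0) {
    GRanges(chrom, IRanges(start0 + 1L, end0))
}

## random interval set on a single toy chromosome of length L (0-based)
randomIntervals <- function(n, L = 10000L, chrom = "toy",
                            max_width = 400L) {
    s <- sample.int(L - 2L, n, replace = TRUE) - 1L
    w <- sample.int(max_width, n, replace = TRUE)
    e <- pmin(L, s + w)
    gr0(chrom, s, e)
}

## per-base occupancy of a single-chromosome set (logical, base i = 0-based
## position i-1)
perBaseMask <- function(gr, L) {
    m <- logical(L)
    s0 <- start(gr) - 1L
    e0 <- end(gr)
    for (i in seq_along(gr))
        if (e0[i] > s0[i]) m[(s0[i] + 1L):e0[i]] <- TRUE
    m
}

## merged intervals recovered from a per-base mask, as 0-based (start, end)
maskToIntervals <- function(m) {
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    data.frame(start = starts[r$values], end = ends[r$values])
}

## per-anchor shared bases with the union of `other`, by brute force
perBaseOverlap <- function(anchor, other, L) {
    mo <- perBaseMask(other, L)
    vapply(seq_along(anchor), function(i) {
        s0 <- start(anchor)[i] - 1L
        e0 <- end(anchor)[i]
        sum(mo[(s0 + 1L):e0])
    }, numeric(1))
}

## exact two-sided signed-rank p by enumeration of all sign assignments
enumSignedRankP <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L) return(1)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- as.vector(signs %*% r)
    p_le <- mean(Ws <= W + 1e-9)
    p_ge <- mean(Ws >= W - 1e-9)
    min(1, 2 * min(p_le, p_ge))
}

## exact two-sided rank-sum p by enumeration of all group labelings
enumRankSumP <- function(x, y) {
    nx <- length(x)
    pooled <- c(x, y)
    r <- rank(pooled)
    U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    combs <- utils::combn(length(pooled), nx)
    Us <- apply(combs, 2L, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
    p_le <- mean(Us <= U_obs + 1e-9)
    p_ge <- mean(Us >= U_obs - 1e-9)
    min(1, 2 * min(p_le, p_ge))
}

## direct BH step-up formula (independent of p.adjust)
stepUpBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

## small but fully-featured cohort for fast unit tests (dots override)
smallSimConfig <- function(seed = 1L, ...) {
    args <- list(seed = seed, n_patients = 6L, n_regions = 120L,
                 chrom_length = 2.4e6, n_genes = 80L,
                 n_proximal_regions = 4L, n_bulk_de_only = 10L,
                 n_cluster_de_only = 6L, n_both_de_background = 4L,
                 n_target_cells = 40L, n_other_cells = 80L,
                 n_cluster_peaks_extra = 10L)
    dots <- list(...)
    args[names(dots)] <- dots
    do.call(simConfig, args)
}

## merged set must cover exactly the same bases as the input, with no two
## output intervals sharing a base (abutting half-open intervals allowed)
mergeMatchesOracle <- function(input, merged, L) {
    if (!identical(perBaseMask(merged, L), perBaseMask(input, L)))
        return(FALSE)
    if (length(merged) < 2L) return(TRUE)
    sum(width(merged)) == sum(perBaseMask(merged, L))
}

## catalog -> universe -> differential -> SOE GRanges, from a cohort
cohortSoes <- function(co, cfg = thresholdConfig()) {
    tss <- geneTssPoints(co@genes)
    enh <- lapply(co@samplePeaks, function(s)
        callSampleEnhancers(s$k27ac, s$k4me1, tss,
                            cfg$tss_min_dist_bp, cfg$anchor))
    grp <- vapply(co@samplePeaks, `[[`, character(1), "group")
    catT <- buildConsensus(enh[grp == "tumor"], "tumor", cfg$min_support)
    catN <- buildConsensus(enh[grp == "normal"], "normal", cfg$min_support)
    uni <- mergeIntervals(c(granges(regions(catT)),
                            granges(regions(catN))))
    mcols(uni)$region_id <- sprintf("univ_%04d", seq_along(uni))
    mapped <- mapCountsToRegions(co@counts, uni)
    diff <- callDifferentialEnhancers(mapped, co@design, cfg = cfg)
    soe_ids <- differentialRegions(diff, "SOE")
    list(universe = uni, mapped = mapped, diff = diff,
         soes = uni[match(soe_ids, mcols(uni)$region_id)],
         catalogs = list(tumor = catT, normal = catN))
}

## default study-scale cohort with its SOE call, computed once per run
.fixtureCache <- new.env(parent = emptyenv())
funnelFixture <- function(seed = 5) {
    key <- paste0("fx", seed)
    if (is.null(.fixtureCache[[key]])) {
        co <- simulateCohort(simConfig(seed = seed))
        .fixtureCache[[key]] <- list(co = co, parts = cohortSoes(co),
                                     tr = groundTruth(co))
    }
    .fixtureCache[[key]]
}

## config list for runPipeline() pointing at a fixture directory
fixtureConfig <- function(dir) {
    list(manifest = file.path(dir, "manifest.tsv"),
         counts = file.path(dir, "counts.tsv"),
         region_lengths = file.path(dir, "region_lengths.tsv"),
         library_sizes = file.path(dir, "library_sizes.tsv"),
         regions_bed = file.path(dir, "regions.bed"),
         design = file.path(dir, "design.tsv"),
         genes = file.path(dir, "genes.tsv"),
         expression = file.path(dir, "expression.tsv"),
         cluster_peaks = file.path(dir, "cluster_peaks.bed"),
         cluster_cells = file.path(dir, "cluster_cells.tsv"),
         cluster_labels = file.path(dir, "cluster_labels.tsv"))
}
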