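test_that("rpkm implements the reads-per-kilobase-per-million formula", {
    se <- regionCounts(matrix(c(200, 0, 10), 3, 1,
                              dimnames = list(c("a", "b", "c"), "s1")),
                       region_lengths = c(2000, 500, 1000),
                       library_sizes = 2e7)
    expect_equal(unname(rpkm(se)[, 1]), c(5, 0, 10 / (1 * 20)))
    se2 <- regionCounts(matrix(10, 1, 1, dimnames = list("a", "s")),
                        1000, 1e6)
    expect_equal(unname(rpkm(se2)[1, 1]), 10)
    expect_error(regionCounts(matrix(1, 1, 1, dimnames = list("a", "s")),
                              0, 1e6), "> 0")
})

simpleCounts <- function(counts, pairs = 3L) {
    samples <- c(paste0("P", 1:pairs, "_T"), paste0("P", 1:pairs, "_N"))
    colnames(counts) <- samples
    se <- regionCounts(counts, rep(1000, nrow(counts)),
                       rep(1e6, ncol(counts)))
    des <- PairedDesign(paste0("P", 1:pairs),
                        paste0("P", 1:pairs, "_T"),
                        paste0("P", 1:pairs, "_N"))
    list(se = se, design = des)
}

test_that("differential classes use strict thresholds on log2fc and padj", {
    # tumor consistently ~4x normal: SOE at the default cutoffs
    cnt <- matrix(c(400, 410, 390, 100, 98, 103,
                    100, 99, 101, 100, 101, 99), 2, 6, byrow = TRUE,
                  dimnames = list(c("up", "flat"), NULL))
    fx <- simpleCounts(cnt)
    d <- callDifferentialEnhancers(fx$se, fx$design)
    expect_equal(d["up", "klass"], "SOE")
    expect_equal(d["flat", "klass"], "NS")
    expect_gt(d["up", "log2fc"], 0.75)
    expect_true(all(d$padj >= d$p))

    # a log2fc exactly at the threshold is NS even at tiny padj
    cnt2 <- matrix(c(200, 200, 200, 100, 100, 100), 1, 6,
                   dimnames = list("edge", NULL))
    fx2 <- simpleCounts(cnt2)
    cfg <- thresholdConfig(pseudocount = 0)
    d2 <- callDifferentialEnhancers(fx2$se, fx2$design, cfg = cfg)
    expect_equal(d2["edge", "log2fc"], 1)
    cfg_edge <- thresholdConfig(pseudocount = 0, enh_log2fc = 1)
    d3 <- callDifferentialEnhancers(fx2$se, fx2$design, cfg = cfg_edge)
    expect_lt(d3["edge", "p"], 0.05)          # constant-shift sentinel p = 0
    expect_equal(d3["edge", "klass"], "NS")   # strict: 1 > 1 is FALSE
    cfg_in <- thresholdConfig(pseudocount = 0, enh_log2fc = 0.99)
    expect_equal(callDifferentialEnhancers(fx2$se, fx2$design,
                                           cfg = cfg_in)["edge", "klass"],
                 "SOE")
})

test_that("swapping tumor and normal maps SOE to CDE exactly", {
    co <- simulateCohort(smallSimConfig(seed = 9))
    des <- co@design
    d1 <- callDifferentialEnhancers(co@counts, des)
    swapped <- PairedDesign(patients(des), normalSamples(des),
                            tumorSamples(des))
    d2 <- callDifferentialEnhancers(co@counts, swapped)
    expect_identical(differentialRegions(d1, "SOE"),
                     differentialRegions(d2, "CDE"))
    expect_identical(differentialRegions(d1, "CDE"),
                     differentialRegions(d2, "SOE"))
    expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-12)
    expect_equal(d1$padj, d2$padj, tolerance = 1e-12)
})

test_that("universe handling: subsetting, missing ids, small designs", {
    co <- simulateCohort(smallSimConfig(seed = 9))
    uni <- rownames(co@counts)[1:50]
    d <- callDifferentialEnhancers(co@counts, co@design, universe = uni)
    expect_equal(d$region_id, uni)
    expect_error(callDifferentialEnhancers(co@counts, co@design,
                                           universe = c(uni, "nope_01")),
                 "nope_01")
    one <- PairedDesign("P01", "P01_T", "P01_N")
    expect_error(callDifferentialEnhancers(co@counts, one), "2 pairs")
})

test_that("saturation is exact at the full cohort and reproducible", {
    co <- simulateCohort(smallSimConfig(seed = 9))
    sat <- saturationAnalysis(co@counts, co@design, k_values = c(2L, 6L),
                              n_replicates = 5, seed = 42)
    expect_true(all(sat$recovery >= 0 & sat$recovery <= 1))
    expect_true(all(sat$recovery[sat$k == 6L] == 1))   # k = n_pairs
    sat2 <- saturationAnalysis(co@counts, co@design, k_values = c(2L, 6L),
                               n_replicates = 5, seed = 42)
    expect_identical(sat, sat2)
    expect_equal(attr(sat, "seed"), 42)
    expect_error(saturationAnalysis(co@counts, co@design,
                                    k_values = 7L, n_replicates = 2),
                 "k_values")
})

test_that("an empty reference SOE set reports recovery 1 with a warning", {
    co <- simulateCohort(smallSimConfig(seed = 9, frac_soe = 0,
                                        frac_cde = 0))
    expect_warning(
        sat <- saturationAnalysis(co@counts, co@design, k_values = 3L,
                                  n_replicates = 3, seed = 1),
        "empty")
    expect_true(all(sat$recovery == 1))
    expect_true(attr(sat, "empty_reference"))
})
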